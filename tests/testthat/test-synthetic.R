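test_that("constant-velocity fixtures carry exact closed-form truth", {
  fx <- make_trajectory("constant_velocity", duration_s = 10, fps = 30,
                        speed = 2, seed = 1)
  expect_equal(fx$truth$total_distance, 20)
  expect_identical(n_frames(fx$table), 301L)
  m <- motion_metrics(fx$table, "snout")
  expect_equal(m$total_distance, fx$truth$total_distance, tolerance = 1e-9)
})

test_that("circular fixtures report the chord sum and the arc length", {
  fx <- make_trajectory("circular", duration_s = 10, fps = 30, radius = 50,
                        seed = 2)
  m <- motion_metrics(fx$table, "snout")
  expect_equal(m$total_distance, fx$truth$total_distance, tolerance = 1e-9)
  # chord sum converges to 2*pi*r from below
  expect_lt(fx$truth$total_distance, fx$truth$arc_length)
  expect_lt(1 - fx$truth$total_distance / fx$truth$arc_length, 1e-4)
})

test_that("generators are pure functions of their seed", {
  a <- make_trajectory("bounded_random_walk", duration_s = 3, seed = 9)
  b <- make_trajectory("bounded_random_walk", duration_s = 3, seed = 9)
  expect_identical(a$table$data, b$table$data)
  expect_identical(a$truth, b$truth)

  c1 <- make_behavior_frames(3, frames_per_cluster = 10, seed = 9)
  c2 <- make_behavior_frames(3, frames_per_cluster = 10, seed = 9)
  expect_identical(c1$table$data, c2$table$data)
  expect_identical(c1$labels, c2$labels)

  s1 <- make_event_signal(duration_s = 2, events = data.frame(start_s = 0.5,
                                                              end_s = 1),
                          seed = 9)
  s2 <- make_event_signal(duration_s = 2, events = data.frame(start_s = 0.5,
                                                              end_s = 1),
                          seed = 9)
  expect_identical(s1$signal$samples, s2$signal$samples)
})

test_that("random walks stay inside the arena bounds", {
  fx <- make_trajectory("bounded_random_walk", duration_s = 30, step_sd = 20,
                        bounds = c(0, 100, 0, 80), seed = 10)
  expect_true(all(fx$table$data$snout_x >= 0 & fx$table$data$snout_x <= 100))
  expect_true(all(fx$table$data$snout_y >= 0 & fx$table$data$snout_y <= 80))
})

test_that("dropout injection marks frames below the cutoff", {
  fx <- make_trajectory("constant_velocity", duration_s = 5, fps = 30,
                        dropout_rate = 0.1, seed = 11)
  lik <- fx$table$data$snout_likelihood
  expect_equal(which(lik < 0.9) - 1L, fx$truth$dropped_frames)
  # conditioning recovers the straight line almost exactly
  cond <- apply_likelihood_cutoff(fx$table, 0.9)
  m <- motion_metrics(cond, "snout")
  expect_equal(m$total_distance, fx$truth$total_distance, tolerance = 1e-6)
})

test_that("behavior scenes carry identity only in posture", {
  fx <- make_behavior_frames(2, frames_per_cluster = 8, noise_sd = 0,
                             seed = 12)
  F <- pairwise_features(fx$table)
  # zero noise: exactly one distinct feature row per cluster
  expect_equal(nrow(unique(round(F, 6))), 2)
  # labels partition the frames by construction
  expect_equal(sort(unique(fx$labels)), 0:1)
  expect_equal(length(fx$labels), n_frames(fx$table))
  # reported separation ratio is finite and positive
  fx2 <- make_behavior_frames(3, frames_per_cluster = 10, seed = 13)
  expect_gt(fx2$separation_ratio, 1)
})

test_that("interleaved scenes keep per-cluster frame counts", {
  fx <- make_behavior_frames(3, frames_per_cluster = 12,
                             order = "interleaved", seed = 14)
  expect_equal(as.integer(table(fx$labels)), rep(12L, 3))
  # interleaving produces more runs than blocks
  runs <- length(rle(fx$labels)$lengths)
  expect_gt(runs, 3)
})

test_that("event-locked signals have the analytic variance structure", {
  ev <- data.frame(start_s = c(5, 20), end_s = c(10, 30))
  # gain 1 -> stationary
  g1 <- make_event_signal(duration_s = 40, events = ev, event_gain = 1,
                          seed = 15)
  v <- as.numeric(g1$signal$samples)
  ratio <- var(v[g1$truth$in_event]) / var(v[!g1$truth$in_event])
  expect_equal(ratio, 1, tolerance = 0.1)
  expect_equal(g1$truth$variance_ratio, 1)

  # gain 5, no noise -> in-event amplitude exactly 5x baseline
  g5 <- make_event_signal(duration_s = 40, events = ev, event_gain = 5,
                          noise_sd = 0, seed = 16)
  v5 <- as.numeric(g5$signal$samples)
  expect_equal(max(abs(v5[g5$truth$in_event])),
               5 * max(abs(v5[!g5$truth$in_event])), tolerance = 1e-3)

  # measured variance ratio tracks the analytic expectation
  g <- make_event_signal(duration_s = 60, events = ev, event_gain = 5,
                         noise_sd = 0.5, seed = 17)
  vg <- as.numeric(g$signal$samples)
  measured <- var(vg[g$truth$in_event]) / var(vg[!g$truth$in_event])
  expect_equal(measured, g$truth$variance_ratio, tolerance = 0.05)
})
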