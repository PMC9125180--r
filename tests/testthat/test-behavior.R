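test_that("pairwise features enumerate unordered part pairs lexicographically", {
  fx <- make_behavior_frames(2, frames_per_cluster = 5, seed = 1)
  F <- pairwise_features(fx$table)   # 4 parts
  expect_equal(ncol(F), 6)
  expect_equal(colnames(F)[1], "part1-part2")
  expect_true(all(F >= 0))

  df <- data.frame(a_x = 0, a_y = 0, b_x = 3, b_y = 4)
  F2 <- pairwise_features(tracking_table(df, fps = 30), c("a", "b"))
  expect_equal(as.numeric(F2), 5)

  expect_error(pairwise_features(tracking_table(df, fps = 30), "a"),
               "at least 2")
  expect_error(pairwise_features(tracking_table(df, fps = 30),
                                 c("a", "nope")), "unknown")
})

test_that("features are invariant to global translation and rotation", {
  fx <- make_behavior_frames(3, frames_per_cluster = 10, seed = 2)
  F0 <- pairwise_features(fx$table)

  shifted <- fx$table
  for (p in bodyparts(shifted)) {
    shifted$data[[paste0(p, "_x")]] <- shifted$data[[paste0(p, "_x")]] + 100
    shifted$data[[paste0(p, "_y")]] <- shifted$data[[paste0(p, "_y")]] - 50
  }
  expect_equal(unclass(pairwise_features(shifted)), unclass(F0),
               tolerance = 1e-12, ignore_attr = TRUE)

  th <- 0.7
  rot <- fx$table
  for (p in bodyparts(rot)) {
    x <- fx$table$data[[paste0(p, "_x")]]
    y <- fx$table$data[[paste0(p, "_y")]]
    rot$data[[paste0(p, "_x")]] <- cos(th) * x - sin(th) * y
    rot$data[[paste0(p, "_y")]] <- sin(th) * x + cos(th) * y
  }
  expect_equal(unclass(pairwise_features(rot)), unclass(F0),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Ward clustering recovers well-separated generative geometries", {
  fx <- make_behavior_frames(2, frames_per_cluster = 30, noise_sd = 1,
                             seed = 3)
  F <- pairwise_features(fx$table)
  probe <- cluster_frames(F, 1e-6)   # full tree, threshold below all merges
  thr <- in_gap_threshold(probe, 2)
  got <- cluster_frames(F, thr)
  expect_equal(got$n_clusters, 2L)
  expect_equal(ari(got$labels, fx$labels), 1)

  # threshold above the root merge -> a single cluster
  root <- max(probe$linkage$height)
  expect_equal(cluster_frames(F, root * 1.01)$n_clusters, 1L)
  expect_error(cluster_frames(F, -1), "positive")
})

test_that("merge tree equals the brute-force Ward agglomeration for small n", {
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(10:40, 1)
    X <- matrix(rnorm(n * 5), n)
    got <- cluster_frames(X, 1)
    want <- ward_oracle(X)
    expect_equal(got$linkage$height, want$heights, tolerance = 1e-9)
    # partitions agree at every agglomeration step
    for (k in c(2, 3, max(2, n %/% 2))) {
      cut_impl <- stats::cutree(got$hclust, k = k)
      cut_orac <- want$partitions[[n - k]]
      expect_equal(ari(cut_impl, cut_orac), 1)
    }
  }
})

test_that("labels are re-indexed by decreasing cluster size", {
  # 5 points near zero, 30 near (100, ...): the big cluster must be label 0
  X <- rbind(matrix(rnorm(5 * 2, 0, 0.1), ncol = 2),
             matrix(rnorm(30 * 2, 100, 0.1), ncol = 2))
  lab <- cluster_frames(X, 50)$labels
  expect_equal(lab[1:5], rep(1L, 5))
  expect_equal(lab[6:35], rep(0L, 30))
  expect_equal(sort(unique(lab)), 0:1)
})

test_that("cluster histogram counts frames and conserves the total", {
  expect_equal(cluster_histogram(c(0L, 0L, 1L)),
               data.frame(cluster = 0:1, n_frames = c(2L, 1L)))
  expect_equal(cluster_histogram(rep(0L, 7))$n_frames, 7L)
  set.seed(4)
  lab <- sample(0:3, 50, replace = TRUE)
  expect_equal(sum(cluster_histogram(lab)$n_frames), 50)
})

test_that("behavior intervals are maximal runs that partition the frames", {
  iv <- behavior_intervals(c(0L, 0L, 1L, 1L, 0L), fps = 2)
  expect_named(iv, c("0", "1"))
  expect_equal(iv[["0"]]$start_frame, c(0L, 4L))
  expect_equal(iv[["0"]]$end_frame, c(1L, 4L))
  expect_equal(iv[["1"]]$start_frame, 2L)
  expect_equal(iv[["1"]]$start_s, 1)
  expect_equal(iv[["1"]]$end_s, 2)

  expect_equal(nrow(behavior_intervals(rep(3L, 9), fps = 30)[["3"]]), 1)

  set.seed(5)
  lab <- sample(0:2, 200, replace = TRUE)
  iv2 <- behavior_intervals(lab, fps = 30)
  frames <- sort(as.integer(unlist(lapply(iv2, function(d)
    unlist(Map(seq, d$start_frame, d$end_frame))), use.names = FALSE)))
  expect_equal(frames, 0:199)
})

test_that("representative frames prefer the cluster medoid", {
  set.seed(6)
  X <- rbind(matrix(rnorm(20 * 3), ncol = 3),
             matrix(rnorm(20 * 3, 50), ncol = 3))
  lab <- rep(0:1, each = 20)
  rep_f <- representative_frames(lab, X, per_cluster = 5, seed = 1)
  # returned indices carry the requested label
  expect_true(all(rep_f[["0"]] < 20))
  expect_true(all(rep_f[["1"]] >= 20))
  # medoid-first ordering matches a brute-force distance-to-medoid sort
  idx <- which(lab == 0)
  D <- as.matrix(dist(X[idx, ]))
  med <- which.min(rowSums(D))
  expect_equal(rep_f[["0"]][1], idx[med] - 1L)
  expect_equal(order(D[med, ])[1:5], match(rep_f[["0"]] + 1L, idx))

  # a singleton cluster returns its only frame however many are requested
  lab2 <- c(0L, rep(1L, 10))
  rep2 <- representative_frames(lab2, matrix(rnorm(22), ncol = 2),
                                per_cluster = 3, seed = 1)
  expect_equal(rep2[["0"]], 0L)
})

test_that("the optional mode filter suppresses single-frame flickers", {
  lab <- c(0L, 0L, 1L, 0L, 0L, 0L)
  expect_equal(mode_filter(lab, 3), rep(0L, 6))
  expect_error(mode_filter(lab, 4), "odd")
})

test_that("behavior outputs round-trip through the CSV/JSON exports", {
  fx <- make_behavior_frames(2, frames_per_cluster = 10, seed = 7)
  F <- pairwise_features(fx$table)
  labels <- cluster_frames(F, in_gap_threshold(cluster_frames(F, 1e-6), 2))
  dir <- withr::local_tempdir()
  paths <- write_behavior(labels, dir)
  lab_csv <- read.csv(paths[["labels"]])
  expect_equal(lab_csv$cluster, labels$labels)
  link_csv <- read.csv(paths[["linkage"]])
  expect_equal(link_csv$height, labels$linkage$height)
  expect_true(file.exists(paths[["intervals"]]))
})
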