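test_that("occupancy maps are conservative 2-D histograms with reproducible edges", {
  t <- toy_table(rep(5, 10), rep(5, 10))
  m <- occupancy(t, "snout", bins = 10, extent = c(0, 10, 0, 10))
  expect_equal(sum(m$counts), 10)
  expect_equal(sum(m$counts == 10), 1)
  expect_equal(dim(m$counts), c(10L, 10L))
  expect_length(m$x_edges, 11)

  # one point per bin center -> all counts 1
  centers <- seq(0.5, 9.5, by = 1)
  g <- expand.grid(x = centers, y = centers)
  tg <- toy_table(g$x, g$y)
  mg <- occupancy(tg, "snout", bins = 10, extent = c(0, 10, 0, 10))
  expect_true(all(mg$counts == 1L))

  # conservation for several bin counts
  fx <- make_trajectory("bounded_random_walk", duration_s = 10, seed = 4)
  for (b in c(5, 10, 50)) {
    mm <- occupancy(fx$table, "snout", bins = b)
    expect_equal(sum(mm$counts), n_frames(fx$table))
  }
  expect_error(occupancy(t, "snout", bins = 0), "bin")
})

test_that("area definitions validate labels, dimensions and emit outlines", {
  fields <- define_fields(area_rect("Obj_1", 430, 35, 90, 75),
                          area_rect("Obj_2", 430, 380, 90, 75))
  expect_named(fields, c("Obj_1", "Obj_2"))
  expect_equal(fields$Obj_1$origin_x, 430)
  expect_equal(nrow(fields$Obj_1$outline), 5)

  expect_error(area_circle("c", 0, 0, 0), "positive")
  expect_error(define_fields(area_rect("a", 0, 0, 1, 1),
                             area_rect("a", 5, 5, 1, 1)), "duplicate")

  # compatibility importer for the 8-element positional vectors
  imp <- import_positional_fields(list(Obj_1 = c(1, 0, 0, 0, 430, 35, 90, 75)))
  expect_equal(imp$Obj_1$origin_y, 35)
  expect_equal(imp$Obj_1$height, 75)
  expect_error(import_positional_fields(list(Obj_1 = 1:3)), "8 elements")
})

test_that("interaction events are maximal runs of in-area frames", {
  x <- rep(0, 20); y <- rep(0, 20)
  x[6:10] <- 5; y[6:10] <- 5        # frames 5..9 (0-based) inside
  t <- toy_table(x, y)
  a <- define_fields(area_rect("A", 4, 4, 2, 2))
  ev <- detect_interactions(t, "snout", a)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 5L)
  expect_equal(ev$end_frame, 9L)
  expect_equal(ev$duration_s, 5 / 30)

  # never entering -> empty but valid
  t2 <- toy_table(rep(100, 10), rep(100, 10))
  ev2 <- detect_interactions(t2, "snout", a)
  expect_equal(nrow(ev2), 0)

  # debounce drops short events
  x3 <- rep(0, 10); x3[c(3, 6:8)] <- 5
  t3 <- toy_table(x3, rep(5, 10))
  ev3 <- detect_interactions(t3, "snout", a, min_frames = 2)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$start_frame, 5L)
})

test_that("boundary rules: rectangles half-open, circles closed", {
  a <- define_fields(area_rect("r", 0, 0, 10, 10),
                     area_circle("c", 50, 50, 5))
  t <- toy_table(c(0, 10, 55, 55.0001), c(0, 10, 50, 50))
  ev <- detect_interactions(t, "snout", a)
  sm <- summarize_interactions(ev, a)
  # frame 0 on the rect origin is inside; frame 1 on the far corner is not
  expect_equal(sm$n_interactions[sm$area == "r"], 1)
  # frame 2 exactly on the radius is inside; frame 3 just outside is not
  expect_equal(ev$start_frame[ev$area == "c"], 2L)
  expect_equal(ev$end_frame[ev$area == "c"], 2L)
})

test_that("event detection matches the per-frame brute-force oracle", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 2000
    x <- 100 + cumsum(rnorm(n, sd = 8))
    y <- 100 + cumsum(rnorm(n, sd = 8))
    areas <- define_fields(
      area_rect("R1", 80, 80, 60, 60),
      area_circle("C1", 120, 110, 40))   # overlaps R1
    t <- toy_table(x, y)
    got <- detect_interactions(t, "snout", areas)
    want <- interaction_oracle(x, y, areas, 30)
    expect_equal(got$area, want$area)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
  }
})

test_that("events are invariant under joint translation of path and areas", {
  set.seed(13)
  x <- 50 + cumsum(rnorm(500, sd = 5)); y <- 50 + cumsum(rnorm(500, sd = 5))
  a0 <- define_fields(area_rect("A", 40, 40, 30, 30))
  a1 <- define_fields(area_rect("A", 40 + 17, 40 - 9, 30, 30))
  e0 <- detect_interactions(toy_table(x, y), "snout", a0)
  e1 <- detect_interactions(toy_table(x + 17, y - 9), "snout", a1)
  expect_equal(e0$start_frame, e1$start_frame)
  expect_equal(e0$end_frame, e1$end_frame)
})

test_that("interaction summaries count events and accumulate durations", {
  t <- toy_table(c(rep(5, 30), rep(100, 30), rep(5, 30)), rep(5, 90))
  a <- define_fields(area_rect("A", 0, 0, 10, 10),
                     area_rect("B", 200, 200, 10, 10))
  ev <- detect_interactions(t, "snout", a)
  sm <- summarize_interactions(ev, a)
  expect_equal(sm$n_interactions[sm$area == "A"], 2)
  expect_equal(sm$total_time_s[sm$area == "A"], 2.0)
  # unvisited areas reported as zero
  expect_equal(sm$n_interactions[sm$area == "B"], 0)
  expect_equal(sm$total_time_s[sm$area == "B"], 0)
  # totals conserve event durations
  expect_equal(sum(sm$total_time_s), sum(ev$duration_s))
})

test_that("events export as BED-like half-open frame intervals", {
  t <- toy_table(c(rep(5, 3), rep(50, 3)), rep(5, 6))
  a <- define_fields(area_rect("A", 0, 0, 10, 10))
  ev <- detect_interactions(t, "snout", a)
  path <- withr::local_tempfile(fileext = ".bed")
  write_events_bed(ev, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 0)
  expect_equal(bed$V3, 3)  # end_frame 2, half-open end 3
})
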