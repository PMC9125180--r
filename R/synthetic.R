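#' Synthetic trajectory with known kinematics
#'
#' Generates a single-body-part tracking table whose traveled distance and
#' speed are known in closed form, so kinematic code can be tested against
#' analytic truth instead of recorded data.
#'
#' Kinds:
#' * `constant_velocity`: straight line at `speed` units/s for `duration_s`
#'   seconds; true distance is exactly `speed * duration_s` (the table has
#'   `duration_s * fps + 1` frames so the step count matches the duration).
#' * `circular`: `revolutions` uniform revolutions of radius `radius`; the
#'   true polyline distance is the chord sum
#'   \eqn{2 r (n-1) \sin(\pi\,rev/(n-1))}, which approaches \eqn{2\pi r\,rev}
#'   as fps grows.
#' * `bounded_random_walk`: Gaussian steps of scale `step_sd`, reflected at
#'   the arena bounds (reflection keeps occupancy well defined); true
#'   distance is the realized sum of step lengths.
#'
#' @param kind trajectory kind (see above).
#' @param duration_s duration in seconds (default 10).
#' @param fps frames per second (default 30).
#' @param speed constant-velocity speed, units/s (default 2).
#' @param heading constant-velocity heading, radians, image convention
#'   (default pi/4).
#' @param radius circle radius (default 50).
#' @param revolutions circle revolutions (default 1).
#' @param step_sd random-walk step scale (default 3).
#' @param bounds arena `c(xmin, xmax, ymin, ymax)` (default 640 x 480 px).
#' @param start start position (default arena center).
#' @param bodypart body-part name (default `"snout"`).
#' @param dropout_rate fraction of interior frames given likelihood 0.05 and
#'   corrupted coordinates, for likelihood-cutoff tests (default 0).
#' @param seed integer seed; fixed seed gives identical output.
#' @return List with `table` (a `tracking_table`, likelihood filled) and
#'   `truth` (`total_distance`, `mean_speed`, plus kind-specific values such
#'   as `arc_length`, and `dropped_frames` when dropouts were injected).
#' @examples
#' fx <- make_trajectory("constant_velocity", duration_s = 10, fps = 30,
#'                       speed = 2, seed = 1)
#' fx$truth$total_distance  # exactly 20
#' @export
make_trajectory <- function(kind = c("constant_velocity", "circular",
                                     "bounded_random_walk"),
                            duration_s = 10, fps = 30, speed = 2,
                            heading = pi / 4, radius = 50, revolutions = 1,
                            step_sd = 3, bounds = c(0, 640, 0, 480),
                            start = NULL, bodypart = "snout",
                            dropout_rate = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, fps > 0)
  set.seed(seed)
  n <- round(duration_s * fps) + 1L
  if (is.null(start))
    start <- c(mean(bounds[1:2]), mean(bounds[3:4]))

  if (kind == "constant_velocity") {
    step <- speed / fps
    i <- 0:(n - 1L)
    x <- start[1L] + i * step * cos(heading)
    y <- start[2L] + i * step * sin(heading)
    truth <- list(total_distance = speed * duration_s, mean_speed = speed)
  } else if (kind == "circular") {
    th <- 2 * pi * revolutions * (0:(n - 1L)) / (n - 1L)
    x <- start[1L] + radius * cos(th)
    y <- start[2L] + radius * sin(th)
    chord <- 2 * radius * (n - 1L) * sin(pi * revolutions / (n - 1L))
    truth <- list(total_distance = chord,
                  arc_length = 2 * pi * radius * revolutions,
                  mean_speed = chord / duration_s)
  } else {
    x <- numeric(n); y <- numeric(n)
    x[1L] <- start[1L]; y[1L] <- start[2L]
    dx <- stats::rnorm(n - 1L, sd = step_sd)
    dy <- stats::rnorm(n - 1L, sd = step_sd)
    for (i in 2:n) {
      x[i] <- reflect(x[i - 1L] + dx[i - 1L], bounds[1L], bounds[2L])
      y[i] <- reflect(y[i - 1L] + dy[i - 1L], bounds[3L], bounds[4L])
    }
    d <- sum(sqrt(diff(x)^2 + diff(y)^2))
    truth <- list(total_distance = d, mean_speed = d / duration_s)
  }

  lik <- rep(1, n)
  if (dropout_rate > 0) {
    interior <- 2:(n - 1L)
    drop <- sort(sample(interior, round(dropout_rate * length(interior))))
    lik[drop] <- 0.05
    x[drop] <- x[drop] + stats::rnorm(length(drop), sd = 100)
    y[drop] <- y[drop] + stats::rnorm(length(drop), sd = 100)
    truth$dropped_frames <- drop - 1L
  }

  df <- data.frame(x = x, y = y, likelihood = lik)
  names(df) <- paste0(bodypart, "_", c("x", "y", "likelihood"))
  list(table = tracking_table(df, fps = fps, units = "pixel"), truth = truth)
}

# reflect a coordinate into [lo, hi]
reflect <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

#' Synthetic behavior scenes with known cluster labels
#'
#' Generates frames in which cluster identity is carried *only* by posture:
#' each cluster has a fixed body-part geometry template (in a body-centric
#' frame), and every frame places its template at a seeded random arena
#' position and orientation before adding coordinate noise. Absolute
#' positions are therefore uninformative, mirroring why pairwise body-part
#' distances are the right feature space.
#'
#' Templates are drawn uniformly in a `template_scale`-sized box and
#' redrawn until every pair of templates is at least
#' `min_template_separation` apart in pairwise-distance feature space; the
#' achieved separation / within-cluster-spread ratio is reported as ground
#' truth (the defaults give a ratio well above 5).
#'
#' @param n_clusters number of behavior clusters (>= 2).
#' @param frames_per_cluster frames generated per cluster (default 40).
#' @param n_parts body parts per frame (default 4: e.g. snout, two ears,
#'   tail base).
#' @param noise_sd coordinate noise in pixels (default 2).
#' @param template_scale size of the template box in pixels (default 60).
#' @param min_template_separation minimum between-template feature-space
#'   distance (default = `template_scale`).
#' @param arena arena bounds `c(xmin, xmax, ymin, ymax)` (default
#'   640 x 480 px).
#' @param fps frames per second recorded in the table (default 30).
#' @param order `"blocks"` (each cluster contiguous) or `"interleaved"`
#'   (alternating short blocks), controlling run structure for
#'   interval-extraction tests.
#' @param seed integer seed.
#' @return List with `table` (a `tracking_table`), `labels` (true 0-based
#'   cluster per frame), `templates` (list of k x 2 matrices) and
#'   `separation_ratio` (min between-template feature distance divided by
#'   mean within-cluster feature deviation).
#' @export
make_behavior_frames <- function(n_clusters, frames_per_cluster = 40L,
                                 n_parts = 4L, noise_sd = 2,
                                 template_scale = 60,
                                 min_template_separation = template_scale,
                                 arena = c(0, 640, 0, 480), fps = 30,
                                 order = c("blocks", "interleaved"),
                                 seed = 1L) {
  order <- match.arg(order)
  if (n_clusters < 2L) stop("need at least 2 clusters")
  set.seed(seed)

  feat <- function(tpl) as.vector(stats::dist(tpl))
  draw_templates <- function() {
    templates <- list()
    accepted <- NULL
    for (i in seq_len(n_clusters)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- matrix(stats::runif(2L * n_parts, 0, template_scale),
                       n_parts, 2L)
        fv <- feat(cand)
        if (is.null(accepted) ||
            min(sqrt(colSums((t(accepted) - fv)^2))) >=
              min_template_separation) {
          templates[[i]] <- cand
          accepted <- rbind(accepted, fv)
          placed <- TRUE
          break
        }
      }
      if (!placed) return(NULL)  # greedy draw cornered itself; restart
    }
    templates
  }
  templates <- NULL
  for (restart in 1:50) {
    templates <- draw_templates()
    if (!is.null(templates)) break
  }
  if (is.null(templates))
    stop("could not draw sufficiently separated templates; lower `min_template_separation`")

  labels <- if (order == "blocks") {
    rep(seq_len(n_clusters) - 1L, each = frames_per_cluster)
  } else {
    blk <- max(1L, frames_per_cluster %/% 4L)
    lab <- rep(rep(seq_len(n_clusters) - 1L, each = blk),
               length.out = n_clusters * frames_per_cluster)
    sort_stable_counts(lab, n_clusters, frames_per_cluster)
  }
  n <- length(labels)

  margin <- template_scale
  px <- stats::runif(n, arena[1L] + margin, arena[2L] - margin)
  py <- stats::runif(n, arena[3L] + margin, arena[4L] - margin)
  th <- stats::runif(n, 0, 2 * pi)

  coords <- matrix(NA_real_, n, 2L * n_parts)
  for (i in seq_len(n)) {
    tpl <- templates[[labels[i] + 1L]]
    R <- matrix(c(cos(th[i]), sin(th[i]), -sin(th[i]), cos(th[i])), 2L, 2L)
    pts <- tpl %*% t(R)
    pts[, 1L] <- pts[, 1L] + px[i]
    pts[, 2L] <- pts[, 2L] + py[i]
    pts <- pts + stats::rnorm(2L * n_parts, sd = noise_sd)
    coords[i, ] <- as.vector(t(pts))
  }
  parts <- paste0("part", seq_len(n_parts))
  df <- as.data.frame(coords)
  names(df) <- as.vector(t(outer(parts, c("_x", "_y"), paste0)))
  tab <- tracking_table(df, fps = fps, units = "pixel")

  Ffull <- t(vapply(seq_len(n), function(i) {
    pts <- matrix(coords[i, ], n_parts, 2L, byrow = TRUE)
    as.vector(stats::dist(pts))
  }, numeric(n_parts * (n_parts - 1L) / 2L)))
  within <- mean(vapply(seq_len(n_clusters) - 1L, function(g) {
    Fg <- Ffull[labels == g, , drop = FALSE]
    mu <- colMeans(Fg)
    mean(sqrt(rowSums(sweep(Fg, 2L, mu)^2)))
  }, numeric(1)))
  fm <- t(vapply(templates, feat, numeric(n_parts * (n_parts - 1L) / 2L)))
  sep <- min(stats::dist(fm))

  list(table = tab, labels = labels, templates = templates,
       separation_ratio = sep / within)
}

# truncate an interleaved label sequence so every cluster keeps exactly
# frames_per_cluster frames, preserving order
sort_stable_counts <- function(lab, n_clusters, per) {
  keep <- logical(length(lab))
  cnt <- integer(n_clusters)
  for (i in seq_along(lab)) {
    g <- lab[i] + 1L
    if (cnt[g] < per) { keep[i] <- TRUE; cnt[g] <- cnt[g] + 1L }
  }
  lab[keep]
}

#' Synthetic event-locked neural signal
#'
#' A sinusoidal carrier in Gaussian noise whose amplitude is multiplied by
#' `event_gain` inside the given event windows — the expected in-event
#' variance \eqn{(g a)^2/2 + \sigma^2} versus baseline \eqn{a^2/2 + \sigma^2}
#' is returned as ground truth, so epoch-extraction code can be checked for
#' event-locked power changes.
#'
#' Event windows are applied on the sample grid with the same half-open
#' round-to-nearest convention as [signal_subset()].
#'
#' @param rate_hz sampling rate (default 1000).
#' @param duration_s signal duration in seconds (default 60).
#' @param events data.frame with `start_s`, `end_s` columns (seconds).
#' @param carrier_hz carrier frequency (default 8, a theta-band rhythm).
#' @param baseline_amp carrier amplitude outside events (default 1).
#' @param event_gain amplitude multiplier inside events (default 5).
#' @param noise_sd Gaussian noise SD (default 0.5).
#' @param seed integer seed.
#' @return List with `signal` (a one-channel `signal_record`) and `truth`
#'   (`var_in`, `var_out`, `variance_ratio`, `in_event` sample mask).
#' @export
make_event_signal <- function(rate_hz = 1000, duration_s = 60, events,
                              carrier_hz = 8, baseline_amp = 1,
                              event_gain = 5, noise_sd = 0.5, seed = 1L) {
  if (any(events$start_s < 0) || any(events$end_s > duration_s))
    stop("events must lie within [0, duration_s]")
  set.seed(seed)
  n <- round(rate_hz * duration_s)
  tt <- (0:(n - 1L)) / rate_hz
  amp <- rep(baseline_amp, n)
  in_event <- logical(n)
  for (i in seq_len(nrow(events))) {
    lo <- round(events$start_s[i] * rate_hz)
    hi <- round(events$end_s[i] * rate_hz)
    if (hi > lo) in_event[(lo + 1L):hi] <- TRUE
  }
  amp[in_event] <- baseline_amp * event_gain
  v <- amp * sin(2 * pi * carrier_hz * tt) + stats::rnorm(n, sd = noise_sd)
  truth <- list(
    var_in = (baseline_amp * event_gain)^2 / 2 + noise_sd^2,
    var_out = baseline_amp^2 / 2 + noise_sd^2,
    in_event = in_event)
  truth$variance_ratio <- truth$var_in / truth$var_out
  list(signal = signal_record(v, rate_hz = rate_hz, channels = "lfp"),
       truth = truth)
}
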