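#' Distance, speed and acceleration of one body part
#'
#' Per-frame displacement is the Euclidean step between consecutive frames;
#' speed is displacement times fps, acceleration the backward difference of
#' speed times fps. The first frame has speed and acceleration 0. No
#' smoothing is applied by default; pose jitter inflates raw speed, so an
#' optional centered moving average over an odd window is available.
#'
#' @param t a `tracking_table`.
#' @param bodypart body-part name.
#' @param window optional [time_window()] applied before computing metrics.
#' @param smooth_window odd integer width of a centered moving-average
#'   smoother applied to x/y before differencing; `NULL` (default) = none.
#' @return A `motion_summary` list: `total_distance`, `mean_speed` (mean over
#'   the n-1 actual steps), `max_speed`, `speed_series`,
#'   `acceleration_series` (both length n), `units`, `fps` and the window
#'   used.
#' @examples
#' df <- data.frame(s_x = c(0, 3, 6), s_y = c(0, 4, 8))
#' motion_metrics(tracking_table(df, fps = 30), "s")$total_distance  # 10
#' @export
motion_metrics <- function(t, bodypart, window = NULL, smooth_window = NULL) {
  stopifnot(inherits(t, "tracking_table"))
  if (!is.null(window)) t <- select_time_window(t, window)
  xy <- part_xy(t, bodypart)
  if (anyNA(xy$x) || anyNA(xy$y))
    stop("missing coordinates in window; run apply_likelihood_cutoff() first")
  x <- xy$x; y <- xy$y
  if (!is.null(smooth_window)) {
    if (smooth_window %% 2 == 0) stop("`smooth_window` must be odd")
    x <- moving_average(x, smooth_window)
    y <- moving_average(y, smooth_window)
  }
  n <- length(x)
  d <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  speed <- d * t$fps
  accel <- c(0, diff(speed)) * t$fps
  structure(
    list(total_distance = sum(d),
         mean_speed = if (n > 1L) mean(speed[-1L]) else 0,
         max_speed = max(speed),
         speed_series = speed,
         acceleration_series = accel,
         units = t$units, fps = t$fps, bodypart = bodypart,
         window = window, n_frames = n),
    class = "motion_summary"
  )
}

#' @export
print.motion_summary <- function(x, ...) {
  u <- x$units
  cat(sprintf("<motion_summary> '%s', %d frames @ %g fps\n",
              x$bodypart, x$n_frames, x$fps))
  cat(sprintf("  total distance: %.4g %s\n", x$total_distance, u))
  cat(sprintf("  mean speed:     %.4g %s/s\n", x$mean_speed, u))
  cat(sprintf("  max speed:      %.4g %s/s\n", x$max_speed, u))
  invisible(x)
}

# centered moving average, window must be odd; edges use a shrinking window
moving_average <- function(v, w) {
  half <- (w - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi])
  }, numeric(1))
}

#' Orientation of the segment between two body parts
#'
#' Per-frame angle of the vector from `ref` to `tip`, computed with `atan2`
#' in *image coordinates* (y grows downward), so +pi/2 points "down" on
#' screen. Head orientation uses neck as `ref` and snout as `tip`; body
#' orientation tail base and snout. Frames where the two parts coincide get
#' `NA` rather than an arbitrary angle. Use [to_math_angle()] for the
#' y-up mathematical convention.
#'
#' @param t a `tracking_table`.
#' @param ref reference (origin) body part.
#' @param tip tip body part.
#' @return An `orientation_series` list: `angle` (radians in (-pi, pi]),
#'   `ref`, `tip`, `fps`.
#' @export
orientation <- function(t, ref, tip) {
  stopifnot(inherits(t, "tracking_table"))
  if (identical(ref, tip)) stop("`ref` and `tip` must be different body parts")
  a <- part_xy(t, ref)
  b <- part_xy(t, tip)
  dx <- b$x - a$x
  dy <- b$y - a$y
  ang <- atan2(dy, dx)
  ang[dx == 0 & dy == 0] <- NA_real_
  ang[!is.na(ang) & ang == -pi] <- pi   # normalize range to (-pi, pi]
  structure(list(angle = ang, ref = ref, tip = tip, fps = t$fps),
            class = "orientation_series")
}

#' Convert an image-convention angle to the mathematical convention
#'
#' Image coordinates have y growing downward; negating the angle yields the
#' usual counter-clockwise-positive, y-up convention.
#'
#' @param angle radians in (-pi, pi] (vector or `orientation_series`).
#' @return Radians in (-pi, pi] in the mathematical convention.
#' @export
to_math_angle <- function(angle) {
  if (inherits(angle, "orientation_series")) angle <- angle$angle
  out <- -angle
  out[!is.na(out) & out == -pi] <- pi
  out
}

#' Trajectory points of one body part
#'
#' The data product behind a trajectory plot: one (x, y, time) triple per
#' frame, with time restarting at 0 for windowed tables (the original frame
#' offset is reported in the `offset_frame` column attribute).
#'
#' @param t a `tracking_table`.
#' @param bodypart body-part name.
#' @return data.frame with columns `x`, `y`, `time_s`; attribute
#'   `offset_frame` carries the window offset.
#' @export
trajectory_points <- function(t, bodypart) {
  stopifnot(inherits(t, "tracking_table"))
  xy <- part_xy(t, bodypart)
  out <- data.frame(x = xy$x, y = xy$y,
                    time_s = (seq_len(n_frames(t)) - 1) / t$fps)
  attr(out, "offset_frame") <- t$start_frame
  out
}

#' Export a motion summary as one-row CSV data
#'
#' @param summaries one `motion_summary` or a list of them.
#' @param names optional animal names (default `animal_1`, ...).
#' @return data.frame, one row per summary: name, n_frames, total_distance,
#'   mean_speed, max_speed, units.
#' @export
motion_summary_table <- function(summaries, names = NULL) {
  if (inherits(summaries, "motion_summary")) summaries <- list(summaries)
  if (is.null(names)) names <- paste0("animal_", seq_along(summaries))
  do.call(rbind, Map(function(s, nm) {
    data.frame(name = nm, n_frames = s$n_frames,
               total_distance = s$total_distance,
               mean_speed = s$mean_speed, max_speed = s$max_speed,
               units = s$units)
  }, summaries, names))
}
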