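#' Construct a neural signal record
#'
#' A continuous multichannel recording (e.g. raw LFP) or a per-sample event
#' series, aligned to the video by an explicit offset: sample 0 of the
#' signal corresponds to time `t0_s` relative to video frame 0. No automatic
#' sync-pulse detection is attempted; the offset is the user's contract.
#'
#' @param samples numeric vector (one channel) or matrix/data.frame with one
#'   column per channel, samples in rows.
#' @param rate_hz sampling rate in Hz, > 0.
#' @param channels optional channel names.
#' @param t0_s offset (seconds) of sample 0 relative to video frame 0
#'   (default 0).
#' @return A `signal_record` list: `samples` (matrix), `rate_hz`,
#'   `channels`, `t0_s`, `duration_s`.
#' @export
signal_record <- function(samples, rate_hz, channels = NULL, t0_s = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("`rate_hz` must be positive")
  if (is.null(channels))
    channels <- colnames(samples) %||% paste0("ch", seq_len(ncol(samples)))
  if (length(channels) != ncol(samples))
    stop("`channels` length must equal the number of signal columns")
  colnames(samples) <- channels
  structure(list(samples = samples, rate_hz = rate_hz, channels = channels,
                 t0_s = t0_s, duration_s = nrow(samples) / rate_hz),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channels x %d samples @ %g Hz (%.3g s, t0 = %g s)\n",
              ncol(x$samples), nrow(x$samples), x$rate_hz, x$duration_s, x$t0_s))
  invisible(x)
}

#' Read / write a signal with a JSON sidecar
#'
#' The signal matrix is stored as a plain CSV (one column per channel) and
#' the metadata (rate, channel names, t0 offset) in a small JSON sidecar
#' `<path>.json`. Vendor acquisition formats are expected to be converted to
#' this layout upstream.
#'
#' @param path CSV path.
#' @return [read_signal()]: a `signal_record`.
#' @export
read_signal <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (!file.exists(meta_path)) stop(sprintf("sidecar not found: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  signal_record(df, rate_hz = meta$rate_hz,
                channels = meta$channels %||% names(df),
                t0_s = meta$t0_s %||% 0)
}

#' @rdname read_signal
#' @param s a `signal_record`.
#' @export
write_signal <- function(s, path) {
  stopifnot(inherits(s, "signal_record"))
  utils::write.csv(as.data.frame(s$samples), path, row.names = FALSE)
  jsonlite::write_json(list(rate_hz = s$rate_hz, channels = s$channels,
                            t0_s = s$t0_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# normalize the many accepted event representations to start_s/end_s + label
as_intervals_s <- function(events, cluster = NULL) {
  if (inherits(events, "behavior_intervals")) {
    keys <- if (is.null(cluster)) names(events) else as.character(cluster)
    out <- do.call(rbind, lapply(keys, function(k) {
      d <- events[[k]]
      if (is.null(d)) stop(sprintf("no behavior cluster '%s'", k))
      data.frame(start_s = d$start_s, end_s = d$end_s,
                 label = paste0("cluster_", k))
    }))
    return(out[order(out$start_s), , drop = FALSE])
  }
  if (is.data.frame(events)) {
    if (all(c("start_s", "end_s") %in% names(events))) {
      lab <- if ("area" %in% names(events)) as.character(events$area)
             else if ("label" %in% names(events)) as.character(events$label)
             else rep("event", nrow(events))
      return(data.frame(start_s = events$start_s, end_s = events$end_s,
                        label = lab))
    }
    stop("event data.frame needs `start_s` and `end_s` columns")
  }
  if (is.matrix(events) && ncol(events) == 2L)
    return(data.frame(start_s = events[, 1L], end_s = events[, 2L],
                      label = "event"))
  stop("unsupported events input; give interaction events, behavior intervals, or a start_s/end_s table")
}

#' Extract signal epochs at behavioral events
#'
#' Cuts the continuous signal at event boundaries. Accepts interaction
#' events ([detect_interactions()]), behavior intervals
#' ([behavior_intervals()]), or any table of start/end timestamps in
#' seconds. Epoch i covers samples
#' `[round((start - t0) * rate), round((end - t0) * rate))` — half-open with
#' round-to-nearest boundaries — and epochs are keyed by chronological
#' number.
#'
#' @param s a `signal_record`.
#' @param events event source (see above).
#' @param cluster when `events` is a `behavior_intervals`, restrict to these
#'   cluster ids (default: all).
#' @return An `epoch_set` list: `epochs` (named list of sample matrices) and
#'   `index` (data.frame epoch, start_s, end_s, n_samples, source_label).
#' @export
signal_subset <- function(s, events, cluster = NULL) {
  stopifnot(inherits(s, "signal_record"))
  iv <- as_intervals_s(events, cluster)
  rate <- s$rate_hz
  n <- nrow(s$samples)
  epochs <- vector("list", nrow(iv))
  idx <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    lo <- round((iv$start_s[i] - s$t0_s) * rate)
    hi <- round((iv$end_s[i] - s$t0_s) * rate)
    if (lo < 0 || hi > n || hi <= lo)
      stop(sprintf("epoch %d [%g, %g) s falls outside the signal (duration %g s after t0 alignment)",
                   i, iv$start_s[i], iv$end_s[i], s$duration_s))
    epochs[[i]] <- s$samples[(lo + 1L):hi, , drop = FALSE]
    idx[[i]] <- data.frame(epoch = i, start_s = iv$start_s[i],
                           end_s = iv$end_s[i], n_samples = hi - lo,
                           source_label = iv$label[i])
  }
  names(epochs) <- as.character(seq_along(epochs))
  structure(list(epochs = epochs, index = do.call(rbind, idx),
                 rate_hz = rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs @ %g Hz\n", length(x$epochs), x$rate_hz))
  print(utils::head(x$index, 10L))
  invisible(x)
}

#' Write an epoch set to disk
#'
#' One CSV per epoch (`epoch_<i>.csv`) plus an `index.csv`.
#'
#' @param e an `epoch_set`.
#' @param dir output directory.
#' @return Invisibly, the index path.
#' @export
write_epochs <- function(e, dir) {
  stopifnot(inherits(e, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(e$epochs))
    utils::write.csv(as.data.frame(e$epochs[[k]]),
                     file.path(dir, sprintf("epoch_%s.csv", k)),
                     row.names = FALSE)
  idx <- file.path(dir, "index.csv")
  utils::write.csv(e$index, idx, row.names = FALSE)
  invisible(idx)
}

#' Spatial map of neural activity
#'
#' Bins the arena like [occupancy()] and averages a per-frame activity
#' series (spike counts per frame, or a continuous signal already reduced to
#' one value per frame) within each spatial bin. Bins never visited are
#' `NA` in the mean grid; the visit-count grid is returned alongside, so
#' the visit-weighted mean of the map recovers the global mean activity
#' exactly.
#'
#' @param t a `tracking_table`.
#' @param bodypart body part giving the animal's position.
#' @param activity numeric vector, one value per frame.
#' @param bins bin count, scalar or `c(nx, ny)`.
#' @param extent optional bounding box `c(xmin, xmax, ymin, ymax)`.
#' @return A `spatial_activity_map` list: `mean` (nx x ny, NA where
#'   unvisited), `counts`, `x_edges`, `y_edges`, `bodypart`.
#' @export
spatial_activity <- function(t, bodypart, activity, bins = 10,
                             extent = NULL) {
  stopifnot(inherits(t, "tracking_table"))
  if (length(activity) != n_frames(t))
    stop(sprintf("`activity` has %d values but the table has %d frames",
                 length(activity), n_frames(t)))
  occ <- occupancy(t, bodypart, bins = bins, extent = extent)
  xy <- part_xy(t, bodypart)
  ix <- bin_index(xy$x, occ$x_edges)
  iy <- bin_index(xy$y, occ$y_edges)
  ok <- !is.na(ix) & !is.na(iy) & !is.na(activity)
  nx <- length(occ$x_edges) - 1L
  ny <- length(occ$y_edges) - 1L
  sums <- matrix(0, nx, ny)
  counts <- matrix(0L, nx, ny)
  for (i in which(ok)) {
    sums[ix[i], iy[i]] <- sums[ix[i], iy[i]] + activity[i]
    counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  }
  mean_grid <- sums / counts
  mean_grid[counts == 0L] <- NA_real_
  structure(list(mean = mean_grid, counts = counts,
                 x_edges = occ$x_edges, y_edges = occ$y_edges,
                 bodypart = bodypart),
            class = "spatial_activity_map")
}
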