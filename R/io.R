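#' Read a tracking CSV file
#'
#' Supports two dialects. `"dlc"` is the DeepLabCut output layout: three
#' header rows named `scorer`, `bodyparts` and `coords` in their first cell,
#' a leading frame-index column, and per body part a cycle of `x`, `y`,
#' `likelihood` columns. `"plain"` is an ordinary one-header-row CSV with
#' columns `<part>_x`, `<part>_y` and optionally `<part>_likelihood`.
#'
#' @param path path to a CSV file.
#' @param dialect `"dlc"` or `"plain"`.
#' @param fps frames per second of the recording (not stored in either
#'   dialect), default 30.
#' @return A validated [tracking_table()] in pixel units with the frame index
#'   rebuilt 0..n-1 and body-part names preserved.
#' @seealso [write_tracking()]
#' @export
read_tracking <- function(path, dialect = c("dlc", "plain"), fps = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))

  if (dialect == "plain") {
    df <- utils::read.csv(path, check.names = FALSE)
    df <- df[, setdiff(names(df), c("frame", "")), drop = FALSE]
    return(tracking_table(df, fps = fps, units = "pixel"))
  }

  raw <- utils::read.csv(path, header = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 4L)
    stop("malformed DLC file: fewer than 4 rows (3 header rows + data)")
  hdr_names <- c("scorer", "bodyparts", "coords")
  for (i in 1:3) {
    if (tolower(raw[i, 1L]) != hdr_names[i])
      stop(sprintf(
        "malformed DLC header: row %d should start with '%s', found '%s'",
        i, hdr_names[i], raw[i, 1L]))
  }
  parts <- as.character(raw[2L, -1L])
  coords <- tolower(as.character(raw[3L, -1L]))
  if (!all(coords %in% c("x", "y", "likelihood")))
    stop("malformed DLC header: 'coords' row must contain only x, y, likelihood")
  body <- raw[-(1:3), -1L, drop = FALSE]
  df <- as.data.frame(lapply(body, as.numeric))
  names(df) <- paste0(parts, "_", coords)
  tracking_table(df, fps = fps, units = "pixel")
}

#' Write a tracking table to CSV
#'
#' Inverse of [read_tracking()]: writes either the DeepLabCut three-row-header
#' dialect or the plain one-header-row dialect. Reading the file back yields
#' bit-identical coordinate values (full double precision is written).
#'
#' @param t a `tracking_table`.
#' @param path output path.
#' @param dialect `"dlc"` or `"plain"`.
#' @param scorer scorer name placed in the DLC header row (default
#'   `"pawtrack"`).
#' @return `path`, invisibly.
#' @export
write_tracking <- function(t, path, dialect = c("dlc", "plain"),
                           scorer = "pawtrack") {
  stopifnot(inherits(t, "tracking_table"))
  dialect <- match.arg(dialect)
  n <- n_frames(t)

  if (dialect == "plain") {
    df <- cbind(frame = seq_len(n) - 1L, t$data)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }

  per <- if (t$has_likelihood) c("x", "y", "likelihood") else c("x", "y")
  cols <- as.vector(t(outer(t$bodyparts, per, paste, sep = "_")))
  data <- t$data[, cols, drop = FALSE]
  lines <- c(
    paste(c("scorer", rep(scorer, length(cols))), collapse = ","),
    paste(c("bodyparts", rep(t$bodyparts, each = length(per))), collapse = ","),
    paste(c("coords", rep(per, length(t$bodyparts))), collapse = ","),
    paste(seq_len(n) - 1L,
          apply(format(data, digits = 17, trim = TRUE, scientific = FALSE),
                1L, paste, collapse = ","),
          sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Condition coordinates below a likelihood cutoff
#'
#' Frames where a body part's tracking likelihood falls below `pcut` are
#' considered unreliable; their x/y values are replaced by linear
#' interpolation between the nearest frames at or above the cutoff
#' (boundary runs take the nearest reliable value). Interpolation, rather
#' than frame dropping, keeps the kinematic series continuous. The
#' operation is idempotent at a fixed cutoff and reports how many frames
#' were conditioned per part in the `"conditioned"` attribute.
#'
#' @param t a `tracking_table` with likelihood columns.
#' @param pcut likelihood cutoff in \eqn{[0, 1]} (0.9 is a common choice for
#'   pose-estimation output).
#' @return A `tracking_table` with conditioned coordinates; attribute
#'   `conditioned` is a named integer vector of per-part conditioned-frame
#'   counts.
#' @export
apply_likelihood_cutoff <- function(t, pcut = 0.9) {
  stopifnot(inherits(t, "tracking_table"))
  if (!t$has_likelihood)
    stop("tracking table has no likelihood columns; nothing to condition")
  if (!is.numeric(pcut) || length(pcut) != 1L || pcut < 0 || pcut > 1)
    stop("`pcut` must be a single value in [0, 1]")

  out <- t
  n <- n_frames(t)
  counts <- integer(length(t$bodyparts))
  names(counts) <- t$bodyparts
  for (p in t$bodyparts) {
    lik <- t$data[[paste0(p, "_likelihood")]]
    ok <- !is.na(lik) & lik >= pcut
    if (!any(ok))
      stop(sprintf("body part '%s' has no frames with likelihood >= %g", p, pcut))
    counts[p] <- sum(!ok)
    if (all(ok)) next
    idx <- seq_len(n)
    for (ax in c("_x", "_y")) {
      col <- paste0(p, ax)
      v <- t$data[[col]]
      out$data[[col]] <- stats::approx(idx[ok], v[ok], xout = idx,
                                       method = "linear", rule = 2)$y
    }
  }
  attr(out, "conditioned") <- counts
  out
}

#' Calibration from a known physical reference
#'
#' A single isotropic scale derived from one object of known physical size
#' visible in the arena (for instance the arena wall).
#'
#' @param reference_length_px length of the reference in pixels, > 0.
#' @param reference_length_cm length of the reference in centimeters, > 0.
#' @return An object of class `calibration_spec` with the derived
#'   `cm_per_px` scale.
#' @examples
#' calibration_spec(590, 59)  # 0.1 cm per pixel
#' @export
calibration_spec <- function(reference_length_px, reference_length_cm) {
  if (!is.numeric(reference_length_px) || reference_length_px <= 0 ||
      !is.numeric(reference_length_cm) || reference_length_cm <= 0)
    stop("both reference lengths must be positive")
  structure(
    list(reference_length_px = reference_length_px,
         reference_length_cm = reference_length_cm,
         cm_per_px = reference_length_cm / reference_length_px),
    class = "calibration_spec"
  )
}

#' Convert a tracking table from pixel to centimeter space
#'
#' Multiplies every coordinate by the calibration scale; likelihoods are
#' untouched. The transformation is isotropic (one scale for both axes).
#'
#' @param t a `tracking_table` in pixel units.
#' @param calibration a [calibration_spec()].
#' @return The tracking table in cm units.
#' @export
pixels_to_cm <- function(t, calibration) {
  stopifnot(inherits(t, "tracking_table"), inherits(calibration, "calibration_spec"))
  if (t$units != "pixel")
    stop("tracking table is already in cm units")
  out <- t
  for (p in t$bodyparts) {
    for (ax in c("_x", "_y")) {
      col <- paste0(p, ax)
      out$data[[col]] <- t$data[[col]] * calibration$cm_per_px
    }
  }
  out$units <- "cm"
  out
}

#' Time window in seconds
#'
#' Half-open interval \eqn{[start, end)} used to restrict analyses to part
#' of a recording.
#'
#' @param start_s start time in seconds, >= 0.
#' @param end_s end time in seconds, > `start_s`.
#' @return An object of class `time_window`.
#' @export
time_window <- function(start_s, end_s) {
  if (!is.numeric(start_s) || !is.numeric(end_s) || start_s < 0 ||
      end_s <= start_s)
    stop("need 0 <= start_s < end_s")
  structure(list(start_s = start_s, end_s = end_s), class = "time_window")
}

#' Select a time window from a tracking table
#'
#' Keeps frames in `[floor(start_s * fps), floor(end_s * fps))`. The frame
#' index is re-zeroed and the original offset accumulated in `start_frame`,
#' so windows of windows keep track of their absolute position.
#'
#' @param t a `tracking_table`.
#' @param w a [time_window()].
#' @return The windowed `tracking_table`.
#' @export
select_time_window <- function(t, w) {
  stopifnot(inherits(t, "tracking_table"), inherits(w, "time_window"))
  n <- n_frames(t)
  if (w$end_s > n / t$fps + 1e-9)
    stop(sprintf("window end %g s exceeds recording duration %g s",
                 w$end_s, n / t$fps))
  lo <- floor(w$start_s * t$fps)          # 0-based, inclusive
  hi <- floor(w$end_s * t$fps)            # 0-based, exclusive
  if (hi <= lo) stop("empty time-window selection")
  out <- t
  out$data <- t$data[(lo + 1L):min(hi, n), , drop = FALSE]
  rownames(out$data) <- NULL
  out$start_frame <- t$start_frame + as.integer(lo)
  out
}
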