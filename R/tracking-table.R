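#' Construct a tracking table
#'
#' The central container of the package: per-frame x/y (and optionally
#' likelihood) coordinates for a set of named body parts, together with the
#' acquisition frame rate and the coordinate units. Coordinates follow the
#' image convention of pose-estimation output: origin at the top-left corner,
#' x increasing rightwards, y increasing *downwards*.
#'
#' @param coords data.frame with, for every body part `p`, columns `p_x` and
#'   `p_y`, and optionally `p_likelihood`. One row per frame, in frame order.
#' @param fps frames per second, > 0.
#' @param units `"pixel"` or `"cm"`.
#' @param start_frame original index of the first row, recorded when a time
#'   window has been selected from a longer recording (default 0).
#' @return An object of class `tracking_table`. Frames are indexed 0-based
#'   and contiguous; access the coordinate data via `$data`, the body-part
#'   names via `bodyparts()`, the frame count via `n_frames()`.
#' @examples
#' df <- data.frame(snout_x = c(0, 3, 6), snout_y = c(0, 4, 8))
#' t <- tracking_table(df, fps = 30)
#' bodyparts(t)
#' @export
tracking_table <- function(coords, fps, units = c("pixel", "cm"),
                           start_frame = 0L) {
  units <- match.arg(units)
  if (!is.data.frame(coords)) stop("`coords` must be a data.frame")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number")

  nm <- names(coords)
  xs <- grep("_x$", nm, value = TRUE)
  parts <- sub("_x$", "", xs)
  if (length(parts) == 0L)
    stop("no '<part>_x' columns found; schema is <part>_x, <part>_y[, <part>_likelihood]")
  for (p in parts) {
    if (!paste0(p, "_y") %in% nm)
      stop(sprintf("schema error: body part '%s' has an x column but no y column", p))
  }
  ys <- grep("_y$", nm, value = TRUE)
  orphan_y <- setdiff(sub("_y$", "", ys), parts)
  if (length(orphan_y))
    stop(sprintf("schema error: body part '%s' has a y column but no x column",
                 orphan_y[1L]))

  has_lik <- all(paste0(parts, "_likelihood") %in% nm)
  lik_cols <- grep("_likelihood$", nm, value = TRUE)
  for (lc in lik_cols) {
    v <- coords[[lc]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(sprintf("likelihood column '%s' has values outside [0, 1]", lc))
  }

  keep <- c(rbind(paste0(parts, "_x"), paste0(parts, "_y")))
  if (length(lik_cols)) keep <- c(keep, lik_cols)
  data <- coords[, intersect(nm, keep), drop = FALSE]
  for (cl in names(data)) data[[cl]] <- as.numeric(data[[cl]])
  rownames(data) <- NULL

  structure(
    list(data = data, bodyparts = parts, fps = fps, units = units,
         start_frame = as.integer(start_frame), has_likelihood = has_lik),
    class = "tracking_table"
  )
}

#' @export
print.tracking_table <- function(x, ...) {
  cat(sprintf("<tracking_table> %d frames @ %g fps, units = %s%s\n",
              n_frames(x), x$fps, x$units,
              if (x$start_frame > 0L)
                sprintf(" (window offset: frame %d)", x$start_frame) else ""))
  cat("  body parts:", paste(x$bodyparts, collapse = ", "), "\n")
  cat("  likelihood:", if (x$has_likelihood) "present" else "absent", "\n")
  invisible(x)
}

#' Body-part names of a tracking table
#' @param t a `tracking_table`.
#' @return Character vector of body-part names.
#' @export
bodyparts <- function(t) {
  stopifnot(inherits(t, "tracking_table"))
  t$bodyparts
}

#' Number of frames in a tracking table
#' @param t a `tracking_table`.
#' @return Integer frame count.
#' @export
n_frames <- function(t) {
  stopifnot(inherits(t, "tracking_table"))
  nrow(t$data)
}

# x/y (and likelihood) columns of one part as a plain data.frame
part_xy <- function(t, bodypart) {
  if (!bodypart %in% t$bodyparts)
    stop(sprintf("unknown body part '%s'; available: %s",
                 bodypart, paste(t$bodyparts, collapse = ", ")))
  out <- data.frame(x = t$data[[paste0(bodypart, "_x")]],
                    y = t$data[[paste0(bodypart, "_y")]])
  lk <- paste0(bodypart, "_likelihood")
  if (lk %in% names(t$data)) out$likelihood <- t$data[[lk]]
  out
}
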