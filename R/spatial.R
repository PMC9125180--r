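#' Rectangular area of interest
#'
#' Rectangle membership is half-open: a point belongs to the rectangle iff
#' `origin <= p < origin + size` on both axes, so adjacent rectangles tile
#' the plane without double counting. Coordinates follow the image
#' convention (origin top-left, y down).
#'
#' @param label unique area name.
#' @param origin_x,origin_y top-left corner (coordinate units).
#' @param width,height positive extents.
#' @return An `area_spec` object.
#' @export
area_rect <- function(label, origin_x, origin_y, width, height) {
  if (width <= 0 || height <= 0) stop("width and height must be positive")
  structure(list(label = label, shape = "rectangle",
                 origin_x = origin_x, origin_y = origin_y,
                 width = width, height = height),
            class = "area_spec")
}

#' Circular area of interest
#'
#' Circle membership is closed: points at exactly the radius are inside.
#'
#' @param label unique area name.
#' @param center_x,center_y center (coordinate units).
#' @param radius positive radius.
#' @return An `area_spec` object.
#' @export
area_circle <- function(label, center_x, center_y, radius) {
  if (radius <= 0) stop("radius must be positive")
  structure(list(label = label, shape = "circle",
                 center_x = center_x, center_y = center_y, radius = radius),
            class = "area_spec")
}

#' Validate a set of areas of interest
#'
#' Checks label uniqueness and attaches a polygonal outline (64-gon for
#' circles) to each area for plotting in pixel space.
#'
#' @param ... `area_spec` objects (or a single list of them).
#' @return A named list of `area_spec`s (class `area_set`), each with an
#'   `outline` data.frame of x/y vertices.
#' @examples
#' define_fields(area_rect("Obj_1", 430, 35, 90, 75),
#'               area_rect("Obj_2", 430, 380, 90, 75))
#' @export
define_fields <- function(...) {
  areas <- list(...)
  if (length(areas) == 1L && !inherits(areas[[1L]], "area_spec"))
    areas <- areas[[1L]]
  if (!length(areas)) stop("no areas given")
  if (!all(vapply(areas, inherits, logical(1), "area_spec")))
    stop("all inputs must be area_spec objects (area_rect()/area_circle())")
  labels <- vapply(areas, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop(sprintf("duplicate area label '%s'", labels[duplicated(labels)][1L]))
  areas <- lapply(areas, function(a) {
    a$outline <- if (a$shape == "rectangle") {
      data.frame(
        x = a$origin_x + c(0, a$width, a$width, 0, 0),
        y = a$origin_y + c(0, 0, a$height, a$height, 0))
    } else {
      th <- seq(0, 2 * pi, length.out = 65L)
      data.frame(x = a$center_x + a$radius * cos(th),
                 y = a$center_y + a$radius * sin(th))
    }
    a
  })
  names(areas) <- labels
  structure(areas, class = "area_set")
}

#' Import areas from the PyRAT positional vector format
#'
#' Compatibility importer, heuristic: PyRAT describes each area as an
#' 8-element numeric vector whose semantics are not fully documented. The
#' last four entries are interpreted as x, y, width, height of a rectangle;
#' the first four are ignored. Use [area_rect()]/[area_circle()] for new
#' code.
#'
#' @param posit named list of 8-element numeric vectors.
#' @return An `area_set` of rectangles.
#' @export
import_positional_fields <- function(posit) {
  if (!length(posit) || is.null(names(posit)))
    stop("`posit` must be a named list of 8-element numeric vectors")
  areas <- lapply(names(posit), function(nm) {
    v <- posit[[nm]]
    if (length(v) != 8L)
      stop(sprintf("area '%s': expected 8 elements, got %d", nm, length(v)))
    area_rect(nm, v[5L], v[6L], v[7L], v[8L])
  })
  define_fields(areas)
}

area_contains <- function(a, x, y) {
  if (a$shape == "rectangle") {
    x >= a$origin_x & x < a$origin_x + a$width &
      y >= a$origin_y & y < a$origin_y + a$height
  } else {
    (x - a$center_x)^2 + (y - a$center_y)^2 <= a$radius^2
  }
}

#' Occupancy map (2-D position histogram)
#'
#' Counts, per spatial bin, the frames in which the chosen body part falls in
#' that bin. Bin edges are returned so rendering is exactly reproducible.
#' Points on the maximum edge are included in the last bin (standard
#' histogram closure); frames with missing coordinates or outside the extent
#' are dropped and reported.
#'
#' @param t a `tracking_table`, or a list of tables (multi-animal average
#'   maps are built from concatenated data).
#' @param bodypart body-part name.
#' @param bins bin count, scalar or `c(nx, ny)`.
#' @param extent optional bounding box `c(xmin, xmax, ymin, ymax)`; default
#'   is the data range.
#' @return An `occupancy_map` list: `counts` (nx x ny matrix, x = rows),
#'   `x_edges`, `y_edges`, `bodypart`, `n_valid`, `n_dropped`.
#' @export
occupancy <- function(t, bodypart, bins = 10, extent = NULL) {
  if (inherits(t, "tracking_table")) t <- list(t)
  xy <- do.call(rbind, lapply(t, part_xy, bodypart = bodypart))
  ok <- !is.na(xy$x) & !is.na(xy$y)
  x <- xy$x[ok]; y <- xy$y[ok]
  if (!length(x)) stop("zero valid frames for occupancy map")
  bins <- as.integer(rep_len(bins, 2L))
  if (any(bins < 1L)) stop("need at least 1 bin per axis")
  if (is.null(extent)) extent <- c(range(x), range(y))
  if (extent[2] <= extent[1]) extent[2] <- extent[1] + 1
  if (extent[4] <= extent[3]) extent[4] <- extent[3] + 1
  x_edges <- seq(extent[1], extent[2], length.out = bins[1] + 1L)
  y_edges <- seq(extent[3], extent[4], length.out = bins[2] + 1L)
  ix <- bin_index(x, x_edges)
  iy <- bin_index(y, y_edges)
  inside <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0L, bins[1], bins[2])
  if (any(inside)) {
    tab <- table(factor(ix[inside], levels = seq_len(bins[1])),
                 factor(iy[inside], levels = seq_len(bins[2])))
    counts <- matrix(as.integer(tab), bins[1], bins[2])
  }
  structure(
    list(counts = counts, x_edges = x_edges, y_edges = y_edges,
         bodypart = bodypart, n_valid = sum(inside),
         n_dropped = length(xy$x) - sum(inside)),
    class = "occupancy_map"
  )
}

# histogram binning: half-open bins, rightmost closed; NA outside edges
bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Detect interaction events with areas of interest
#'
#' A frame interacts with an area iff the chosen body part lies inside it
#' (rectangles half-open, circles closed; see [area_rect()]). Maximal runs
#' of consecutive interacting frames become one event; events from all areas
#' are merged and sorted chronologically. An empty result (no visits) is
#' valid.
#'
#' @param t a `tracking_table`.
#' @param bodypart body part whose position defines the interaction
#'   (typically the snout).
#' @param areas an `area_set` from [define_fields()].
#' @param min_frames optional debounce: drop events shorter than this many
#'   frames (default 1 = keep all).
#' @return data.frame of class `interaction_events` with columns `area`,
#'   `start_frame`, `end_frame` (inclusive, 0-based), `start_s`, `end_s`,
#'   `duration_s` (= (end - start + 1)/fps).
#' @export
detect_interactions <- function(t, bodypart, areas, min_frames = 1L) {
  stopifnot(inherits(t, "tracking_table"))
  if (!inherits(areas, "area_set")) areas <- define_fields(areas)
  if (!length(areas)) stop("`areas` must be non-empty")
  xy <- part_xy(t, bodypart)
  fps <- t$fps
  ev <- list()
  for (a in areas) {
    inside <- area_contains(a, xy$x, xy$y)
    inside[is.na(inside)] <- FALSE
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_frames
    if (!any(keep)) next
    ev[[a$label]] <- data.frame(
      area = a$label,
      start_frame = starts[keep] - 1L,
      end_frame = ends[keep] - 1L)
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(area = character(), start_frame = integer(),
               end_frame = integer())
  out <- out[order(out$start_frame, out$area), , drop = FALSE]
  rownames(out) <- NULL
  out$start_s <- out$start_frame / fps
  out$end_s <- (out$end_frame + 1L) / fps
  out$duration_s <- (out$end_frame - out$start_frame + 1L) / fps
  attr(out, "fps") <- fps
  attr(out, "area_labels") <- names(areas)
  class(out) <- c("interaction_events", "data.frame")
  out
}

#' Summarize interaction events per area
#'
#' @param events an `interaction_events` data.frame from
#'   [detect_interactions()].
#' @param areas optional `area_set` (or label vector) so areas with no
#'   events are reported as zero.
#' @return data.frame with one row per area: `area`, `n_interactions`,
#'   `total_time_s`.
#' @export
summarize_interactions <- function(events, areas = NULL) {
  labels <- if (inherits(areas, "area_set")) names(areas)
            else if (is.character(areas)) areas
            else attr(events, "area_labels")
  if (is.null(labels)) labels <- unique(events$area)
  out <- data.frame(
    area = labels,
    n_interactions = vapply(labels, function(l) sum(events$area == l),
                            integer(1)),
    total_time_s = vapply(labels, function(l)
      sum(events$duration_s[events$area == l]), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Export interaction events as half-open frame intervals (BED-like)
#'
#' Writes `area`, `start`, `end` with `end = end_frame + 1`, i.e. half-open
#' intervals on the frame axis, the convention of genome-interval formats.
#'
#' @param events an `interaction_events` data.frame.
#' @param path output path (TSV, no header).
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  utils::write.table(
    data.frame(area = events$area, start = events$start_frame,
               end = events$end_frame + 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
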