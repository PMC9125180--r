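#' Pairwise body-part distance features
#'
#' The frame-wise feature representation for unsupervised behavior
#' classification: the Euclidean distance between every unordered pair of
#' the chosen body parts. Distances are invariant to where the animal is in
#' the arena and to its heading, so only posture carries information.
#' Columns are ordered lexicographically by pair and named `a-b`.
#'
#' @param t a `tracking_table` with no missing coordinates (condition with
#'   [apply_likelihood_cutoff()] first).
#' @param bp_list at least two body-part names (e.g. snout, both ears and
#'   the tail base).
#' @param standardize z-score each distance column (default `FALSE`: raw
#'   distances, which weights long body segments more in Ward clustering —
#'   see the methods vignette).
#' @return Numeric matrix, frames x k(k-1)/2 columns, class
#'   `feature_matrix`; attribute `units` echoes the coordinate units.
#' @export
pairwise_features <- function(t, bp_list = bodyparts(t), standardize = FALSE) {
  stopifnot(inherits(t, "tracking_table"))
  bp_list <- sort(unique(bp_list))
  if (length(bp_list) < 2L) stop("need at least 2 body parts")
  missing_parts <- setdiff(bp_list, t$bodyparts)
  if (length(missing_parts))
    stop(sprintf("unknown body part(s): %s; available: %s",
                 paste(missing_parts, collapse = ", "),
                 paste(t$bodyparts, collapse = ", ")))
  pairs <- utils::combn(bp_list, 2L)
  F <- apply(pairs, 2L, function(pr) {
    a <- part_xy(t, pr[1L]); b <- part_xy(t, pr[2L])
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  })
  F <- matrix(F, nrow = n_frames(t))
  colnames(F) <- apply(pairs, 2L, paste, collapse = "-")
  if (anyNA(F))
    stop("missing coordinates in features; run apply_likelihood_cutoff() first")
  if (standardize) {
    sd0 <- apply(F, 2L, stats::sd)
    sd0[sd0 == 0] <- 1
    F <- scale(F, center = TRUE, scale = sd0)
    attr(F, "scaled:center") <- NULL
    attr(F, "scaled:scale") <- NULL
  }
  attr(F, "units") <- t$units
  attr(F, "fps") <- t$fps
  class(F) <- c("feature_matrix", class(F))
  F
}

#' Ward agglomerative clustering of frames
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances between
#' feature rows. The merge tree is cut at `distance_threshold`: every merge
#' whose height exceeds the threshold is undone, and the resulting connected
#' components are the behavior clusters. Labels are re-indexed by decreasing
#' cluster size (ties broken by first-occurring frame), 0-based, so cluster
#' 0 is always the most populated behavior.
#'
#' The threshold is in Ward merge-height units of the feature space: the
#' same number means a different granularity for pixel- and cm-calibrated
#' features (units are echoed in the result).
#'
#' @param features a `feature_matrix` (or any numeric matrix, frames in
#'   rows).
#' @param distance_threshold positive cut height (Ward units).
#' @return A `behavior_labels` list: `labels` (0-based integer per frame),
#'   `n_clusters`, `linkage` (data.frame child1/child2/height/size with
#'   0-based ids, leaves 0..n-1 then internal nodes n..2n-2),
#'   `distance_threshold`, `units`, and the underlying `hclust` object (for
#'   dendrograms).
#' @export
cluster_frames <- function(features, distance_threshold) {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 frames to cluster")
  if (!is.numeric(distance_threshold) || distance_threshold <= 0)
    stop("`distance_threshold` must be positive")
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  raw <- stats::cutree(hc, h = distance_threshold)
  labels <- reindex_by_size(raw)
  structure(
    list(labels = labels,
         n_clusters = length(unique(labels)),
         linkage = linkage_table(hc),
         distance_threshold = distance_threshold,
         units = attr(features, "units") %||% "unknown",
         fps = attr(features, "fps"),
         hclust = hc),
    class = "behavior_labels"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# relabel clusters 0..C-1 by decreasing size; ties -> earliest first frame
reindex_by_size <- function(raw) {
  ids <- unique(raw)
  size <- vapply(ids, function(i) sum(raw == i), integer(1))
  first <- vapply(ids, function(i) which(raw == i)[1L], integer(1))
  ord <- ids[order(-size, first)]
  match(raw, ord) - 1L
}

# hclust merge matrix -> scipy-style linkage table with 0-based node ids
linkage_table <- function(hc) {
  n <- length(hc$order)
  m <- hc$merge
  id <- function(x) ifelse(x < 0, -x - 1L, n - 1L + x)
  sizes <- integer(nrow(m))
  node_size <- function(x) if (x < 0) 1L else sizes[x]
  for (i in seq_len(nrow(m)))
    sizes[i] <- node_size(m[i, 1L]) + node_size(m[i, 2L])
  data.frame(child1 = id(m[, 1L]), child2 = id(m[, 2L]),
             height = hc$height, size = sizes)
}

#' @export
print.behavior_labels <- function(x, ...) {
  cat(sprintf("<behavior_labels> %d frames, %d clusters (threshold %g, %s units)\n",
              length(x$labels), x$n_clusters, x$distance_threshold, x$units))
  print(cluster_histogram(x))
  invisible(x)
}

#' Frames per behavior cluster
#'
#' The per-cluster frame counts behind the cluster-size histogram; clusters
#' with very few frames are candidates for misclassification and deserve
#' visual inspection.
#'
#' @param labels a `behavior_labels` object (or an integer label vector).
#' @return data.frame `cluster`, `n_frames`, sorted by cluster id; counts
#'   sum to the number of frames.
#' @export
cluster_histogram <- function(labels) {
  lab <- if (inherits(labels, "behavior_labels")) labels$labels else labels
  ids <- sort(unique(lab))
  data.frame(cluster = ids,
             n_frames = vapply(ids, function(i) sum(lab == i), integer(1)))
}

#' Time intervals of each behavior
#'
#' Maximal runs of consecutive frames carrying the same cluster label, per
#' cluster — the bridge from per-frame classification to event-based neural
#' analysis ([signal_subset()]).
#'
#' @param labels a `behavior_labels` object or integer label vector.
#' @param fps frames per second; taken from `labels` when available.
#' @return A named list (class `behavior_intervals`), one element per
#'   cluster id, each a data.frame `start_frame`, `end_frame` (inclusive),
#'   `start_s`, `end_s` (half-open seconds). The union of all intervals
#'   partitions the frames.
#' @export
behavior_intervals <- function(labels, fps = NULL) {
  lab <- if (inherits(labels, "behavior_labels")) labels$labels else labels
  if (is.null(fps) && inherits(labels, "behavior_labels")) fps <- labels$fps
  if (is.null(fps)) stop("`fps` is required")
  r <- rle(as.integer(lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(cluster = r$values, start_frame = starts - 1L,
                     end_frame = ends - 1L)
  ids <- sort(unique(runs$cluster))
  out <- lapply(ids, function(i) {
    d <- runs[runs$cluster == i, c("start_frame", "end_frame"), drop = FALSE]
    rownames(d) <- NULL
    d$start_s <- d$start_frame / fps
    d$end_s <- (d$end_frame + 1L) / fps
    d
  })
  names(out) <- as.character(ids)
  structure(out, fps = fps, class = "behavior_intervals")
}

#' Optional temporal mode filter for per-frame labels
#'
#' Each frame is classified independently; a sliding-mode filter suppresses
#' single-frame label flickers. Off by default throughout the package.
#'
#' @param labels integer label vector or `behavior_labels`.
#' @param window odd window width (default 5).
#' @return Filtered integer label vector.
#' @export
mode_filter <- function(labels, window = 5L) {
  lab <- if (inherits(labels, "behavior_labels")) labels$labels else labels
  if (window %% 2L == 0L) stop("`window` must be odd")
  half <- (window - 1L) %/% 2L
  n <- length(lab)
  vapply(seq_len(n), function(i) {
    seg <- lab[max(1L, i - half):min(n, i + half)]
    tb <- table(seg)
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
}

#' Representative frames of each behavior cluster
#'
#' Frame indices a researcher should look at to name a cluster: frames are
#' ranked by distance to the cluster medoid in feature space (medoid first),
#' and the top `per_cluster` are returned. Exact distance ties are broken by
#' a seeded random order so the choice is reproducible.
#'
#' @param labels a `behavior_labels` object or integer label vector.
#' @param features the `feature_matrix` the labels were computed from.
#' @param per_cluster frames to return per cluster (>= 1); clusters smaller
#'   than this return all their frames.
#' @param seed integer seed for tie-breaking.
#' @return Named list: cluster id -> integer vector of 0-based frame
#'   indices, nearest-to-medoid first.
#' @export
representative_frames <- function(labels, features, per_cluster = 3L,
                                  seed = 1L) {
  lab <- if (inherits(labels, "behavior_labels")) labels$labels else labels
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != length(lab))
    stop("feature rows must match label length")
  if (per_cluster < 1L) stop("`per_cluster` must be >= 1")
  ids <- sort(unique(lab))
  out <- lapply(ids, function(i) {
    idx <- which(lab == i)
    Fi <- features[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(Fi))
    medoid <- which.min(rowSums(D))
    d <- D[medoid, ]
    jitter_ord <- local({ set.seed(seed + i); sample.int(length(idx)) })
    ord <- order(d, jitter_ord)
    idx[ord][seq_len(min(per_cluster, length(idx)))] - 1L
  })
  names(out) <- as.character(ids)
  out
}

#' Write behavior outputs to CSV/JSON
#'
#' @param labels a `behavior_labels` object.
#' @param dir output directory (created if needed).
#' @param embedding optional `Embedding` matrix to write alongside.
#' @return Invisibly, the paths written: per-frame labels
#'   (`labels.csv`), linkage table (`linkage.csv`), intervals
#'   (`intervals.json`), and optionally `embedding.csv`.
#' @export
write_behavior <- function(labels, dir, embedding = NULL) {
  stopifnot(inherits(labels, "behavior_labels"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(dir, "labels.csv"),
             linkage = file.path(dir, "linkage.csv"),
             intervals = file.path(dir, "intervals.json"))
  utils::write.csv(data.frame(frame = seq_along(labels$labels) - 1L,
                              cluster = labels$labels),
                   paths["labels"], row.names = FALSE)
  utils::write.csv(labels$linkage, paths["linkage"], row.names = FALSE)
  if (!is.null(labels$fps)) {
    iv <- behavior_intervals(labels)
    jsonlite::write_json(lapply(iv, function(d) unname(split(d, seq_len(nrow(d))))),
                         paths["intervals"], auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(embedding)) {
    paths <- c(paths, embedding = file.path(dir, "embedding.csv"))
    utils::write.csv(data.frame(frame = seq_len(nrow(embedding)) - 1L,
                                dim1 = embedding[, 1L], dim2 = embedding[, 2L]),
                     paths["embedding"], row.names = FALSE)
  }
  invisible(paths)
}
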