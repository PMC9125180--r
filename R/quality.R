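#' Embedding-quality metrics (KNN, KNC, CPD)
#'
#' Three complementary scores of how faithfully a 2-D embedding preserves
#' the structure of the high-dimensional feature space:
#'
#' * **KNN** (local): for each point, the fraction of its `k_local` nearest
#'   neighbors in feature space that are also among its `k_local` nearest
#'   neighbors in the embedding, averaged over points.
#' * **KNC** (mesoscale): for each class, the fraction of its `k_class`
#'   nearest class centroids in feature space preserved among its `k_class`
#'   nearest centroids in the embedding, averaged over classes. Classes are
#'   the behavior clusters themselves.
#' * **CPD** (global): Spearman correlation between pairwise distances in
#'   feature space and in the embedding, over a seeded random subsample of
#'   points.
#'
#' All three are invariant under rotation, translation and uniform scaling
#' of the embedding (they depend only on distance ranks).
#'
#' @param features the `feature_matrix` (n x d).
#' @param embedding the n x 2 embedding.
#' @param labels a `behavior_labels` object or integer class vector
#'   (required for KNC; with fewer than 2 classes KNC is `NA`).
#' @param k_local neighbors for KNN (default 10).
#' @param k_class centroids for KNC (default `min(4, n_classes - 1)`).
#' @param cpd_subsample points sampled for CPD (default 1000).
#' @param seed seed for the CPD subsample.
#' @return An `embedding_quality` list: `knn`, `knc`, `cpd` plus the
#'   evaluation parameters used.
#' @export
embedding_quality <- function(features, embedding, labels = NULL,
                              k_local = 10L, k_class = NULL,
                              cpd_subsample = 1000L, seed = 1L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  E <- unclass(as.matrix(embedding))
  n <- nrow(features)
  if (nrow(E) != n) stop("embedding rows must match feature rows")
  if (k_local >= n) stop("`k_local` must be smaller than the number of points")

  DF <- as.matrix(stats::dist(unclass(features)))
  DE <- as.matrix(stats::dist(E))

  knn <- mean(vapply(seq_len(n), function(i) {
    nf <- k_smallest(DF[i, ], i, k_local)
    ne <- k_smallest(DE[i, ], i, k_local)
    length(intersect(nf, ne)) / k_local
  }, numeric(1)))

  lab <- if (inherits(labels, "behavior_labels")) labels$labels else labels
  knc <- NA_real_
  if (!is.null(lab)) {
    ids <- sort(unique(lab))
    C <- length(ids)
    if (C >= 2L) {
      if (is.null(k_class)) k_class <- min(4L, C - 1L)
      if (k_class >= C) stop("`k_class` must be smaller than the number of classes")
      cf <- t(vapply(ids, function(g) colMeans(features[lab == g, , drop = FALSE]),
                     numeric(ncol(features))))
      ce <- t(vapply(ids, function(g) colMeans(E[lab == g, , drop = FALSE]),
                     numeric(2L)))
      DCf <- as.matrix(stats::dist(cf))
      DCe <- as.matrix(stats::dist(ce))
      knc <- mean(vapply(seq_len(C), function(i) {
        nf <- k_smallest(DCf[i, ], i, k_class)
        ne <- k_smallest(DCe[i, ], i, k_class)
        length(intersect(nf, ne)) / k_class
      }, numeric(1)))
    }
  }

  m <- min(cpd_subsample, n)
  sub <- local({ set.seed(seed); sort(sample.int(n, m)) })
  up <- upper.tri(matrix(0, m, m))
  cpd <- stats::cor(DF[sub, sub][up], DE[sub, sub][up], method = "spearman")

  structure(list(knn = knn, knc = knc, cpd = cpd,
                 k_local = k_local, k_class = k_class,
                 cpd_subsample = m, seed = seed),
            class = "embedding_quality")
}

# indices of the k smallest entries of d, excluding position `self`
k_smallest <- function(d, self, k) {
  d[self] <- Inf
  order(d)[seq_len(k)]
}

#' @export
print.embedding_quality <- function(x, ...) {
  cat(sprintf("<embedding_quality> KNN = %.3f (k = %d), KNC = %s (k = %s), CPD = %.3f (m = %d)\n",
              x$knn, x$k_local,
              if (is.na(x$knc)) "NA" else sprintf("%.3f", x$knc),
              if (is.null(x$k_class)) "-" else x$k_class,
              x$cpd, x$cpd_subsample))
  invisible(x)
}
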