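#' Heuristic t-SNE configuration
#'
#' Hyperparameters follow the large-dataset heuristics that make t-SNE
#' embeddings of frame-wise posture features stable: PCA initialization,
#' learning rate \eqn{\eta = n/12} and perplexity \eqn{n/100}, where n is
#' the number of frames. The perplexity formula degenerates for small n
#' (the effective neighborhood collapses), so it is clamped from below to
#' 5 — the clamp engages below n = 500. The learning rate follows the
#' formula unclamped; it is a step size, and small values for short
#' recordings merely slow convergence.
#'
#' @param n number of data points (frames).
#' @param learning_rate override for \eqn{\eta} (default: n/12).
#' @param perplexity override (default: max(n/100, 5)). Must satisfy
#'   `perplexity < (n - 1)/3`.
#' @param seed integer seed (t-SNE with PCA initialization is deterministic,
#'   but the seed also covers the optional random initialization).
#' @param n_iter gradient-descent iterations (default 750, of which the
#'   first 250 use early exaggeration).
#' @param init `"pca"` (default) or `"random"`.
#' @return A `tsne_config` list.
#' @examples
#' tsne_config(1200)  # learning_rate 100, perplexity 12
#' tsne_config(300)   # learning_rate 25, perplexity clamped to 5
#' @export
tsne_config <- function(n, learning_rate = NULL, perplexity = NULL,
                        seed = 42L, n_iter = 750L,
                        init = c("pca", "random")) {
  init <- match.arg(init)
  if (n < 30L) stop("need at least 30 data points for a t-SNE embedding")
  if (is.null(learning_rate)) learning_rate <- n / 12
  if (is.null(perplexity)) perplexity <- max(n / 100, 5)
  if (learning_rate <= 0) stop("learning rate must be positive")
  if (perplexity < 1 || perplexity >= (n - 1) / 3)
    stop(sprintf("perplexity must lie in [1, (n-1)/3) = [1, %g)", (n - 1) / 3))
  structure(list(n = as.integer(n), learning_rate = learning_rate,
                 perplexity = perplexity, seed = as.integer(seed),
                 n_iter = as.integer(n_iter), init = init),
            class = "tsne_config")
}

#' 2-D t-SNE embedding of frame features
#'
#' Exact (dense) t-distributed stochastic neighbor embedding: input
#' similarities from a Gaussian kernel with per-point bandwidth calibrated
#' to the target perplexity by bisection, output similarities from the
#' Student-t kernel, minimized by gradient descent with momentum, adaptive
#' gains and early exaggeration. Initialization uses the first two
#' principal components scaled to a standard deviation of 1e-4, which
#' preserves the global arrangement of the data; with that initialization
#' the embedding is a deterministic function of the input.
#'
#' @param features a `feature_matrix` (frames x distances) or any numeric
#'   matrix.
#' @param cfg a [tsne_config()]; default configuration is built from
#'   `nrow(features)`.
#' @return n x 2 matrix (class `tsne_embedding`), columns `dim1`, `dim2`;
#'   attribute `config` echoes the configuration used.
#' @export
tsne_embed <- function(features, cfg = tsne_config(nrow(features))) {
  if (!is.matrix(features)) features <- as.matrix(features)
  X <- unclass(features)
  attributes(X)[c("units", "fps")] <- NULL
  n <- nrow(X)
  if (n != cfg$n)
    stop(sprintf("config built for n = %d but features have %d rows", cfg$n, n))

  P <- tsne_input_similarities(X, cfg$perplexity)

  Y <- if (cfg$init == "pca") {
    sc <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x
    if (ncol(sc) < 2L) sc <- cbind(sc, 0)
    Y0 <- sc[, 1:2, drop = FALSE]
    s1 <- stats::sd(Y0[, 1L])
    if (s1 > 0) Y0 <- Y0 / s1 * 1e-4
    Y0
  } else {
    set.seed(cfg$seed)
    matrix(stats::rnorm(2L * n, sd = 1e-4), n, 2L)
  }

  exaggeration <- 12
  stop_exag <- min(250L, cfg$n_iter)
  eta <- cfg$learning_rate
  momentum <- 0.5
  gains <- matrix(1, n, 2L)
  update <- matrix(0, n, 2L)
  min_gain <- 0.01

  Pex <- P * exaggeration
  for (iter in seq_len(cfg$n_iter)) {
    if (iter == stop_exag + 1L) Pex <- P
    if (iter == 251L) momentum <- 0.8

    sq <- rowSums(Y^2)
    W <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))  # Student-t kernel
    diag(W) <- 0
    Q <- W / sum(W)
    M <- (Pex - Q) * W
    grad <- 4 * (rowSums(M) * Y - M %*% Y)

    dir_same <- sign(grad) == sign(update)
    gains <- ifelse(dir_same, gains * 0.8, gains + 0.2)
    gains[gains < min_gain] <- min_gain
    update <- momentum * update - eta * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2L, colMeans(Y))
  }

  colnames(Y) <- c("dim1", "dim2")
  attr(Y, "config") <- cfg
  class(Y) <- c("tsne_embedding", class(Y))
  Y
}

# symmetrized input similarities at the target perplexity (bisection on
# the per-point Gaussian precision)
tsne_input_similarities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { H <- 0; p[] <- 0 } else {
        H <- log(s) + beta * sum(di * p) / s
        p <- p / s
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else          { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.xmin] <- .Machine$double.xmin
  P
}
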