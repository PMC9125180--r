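# Independent brute-force oracles used to validate the implementation paths.
# These deliberately share no code with the package internals.

# Linear interpolation over sub-cutoff gaps, walking each gap explicitly.
interp_gap_oracle <- function(v, ok) {
  out <- v
  n <- length(v)
  valid <- which(ok)
  for (i in seq_len(n)) {
    if (ok[i]) next
    left <- valid[valid < i]
    right <- valid[valid > i]
    if (!length(left)) {
      out[i] <- v[right[1L]]
    } else if (!length(right)) {
      out[i] <- v[left[length(left)]]
    } else {
      l <- left[length(left)]; r <- right[1L]
      out[i] <- v[l] + (v[r] - v[l]) * (i - l) / (r - l)
    }
  }
  out
}

# Per-frame region membership + run-length event detection, written from the
# stated geometry rules (rectangles half-open, circles closed).
interaction_oracle <- function(x, y, areas, fps) {
  rows <- list()
  for (a in areas) {
    if (a$shape == "rectangle") {
      inside <- x >= a$origin_x & x < a$origin_x + a$width &
        y >= a$origin_y & y < a$origin_y + a$height
    } else {
      inside <- sqrt((x - a$center_x)^2 + (y - a$center_y)^2) <= a$radius
    }
    inside[is.na(inside)] <- FALSE
    i <- 1L
    n <- length(inside)
    while (i <= n) {
      if (inside[i]) {
        j <- i
        while (j < n && inside[j + 1L]) j <- j + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(area = a$label, start_frame = i - 1L, end_frame = j - 1L)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(rows))
    return(data.frame(area = character(), start_frame = integer(),
                      end_frame = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start_frame, out$area), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(n^3) Ward agglomeration recomputing the merge criterion
# d(A,B) = sqrt(2|A||B|/(|A|+|B|)) * ||mean(A) - mean(B)|| for every
# candidate pair at every step. Returns merge heights and the partition
# (as a label vector) after each merge.
ward_oracle <- function(X) {
  n <- nrow(X)
  members <- as.list(seq_len(n))
  means <- X
  sizes <- rep(1L, n)
  active <- seq_len(n)
  heights <- numeric(n - 1L)
  partitions <- vector("list", n - 1L)
  lab <- seq_len(n)
  for (s in seq_len(n - 1L)) {
    best <- Inf; bi <- NA; bj <- NA
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        dm <- means[i, ] - means[j, ]
        d <- sqrt(2 * sizes[i] * sizes[j] / (sizes[i] + sizes[j]) *
                    sum(dm^2))
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights[s] <- best
    means[bi, ] <- (sizes[bi] * means[bi, ] + sizes[bj] * means[bj, ]) /
      (sizes[bi] + sizes[bj])
    sizes[bi] <- sizes[bi] + sizes[bj]
    members[[bi]] <- c(members[[bi]], members[[bj]])
    lab[members[[bi]]] <- min(members[[bi]])
    active <- setdiff(active, bj)
    partitions[[s]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# canonical signature of a partition: relabel groups by first occurrence
partition_signature <- function(lab) {
  paste(match(lab, unique(lab)), collapse = ",")
}

# unwrap a wrapped angle series to a continuous one
unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1L], d))
}

# tiny deterministic tracking table builder
toy_table <- function(x, y, likelihood = NULL, fps = 30, part = "snout") {
  df <- data.frame(a = x, b = y)
  names(df) <- paste0(part, c("_x", "_y"))
  if (!is.null(likelihood)) df[[paste0(part, "_likelihood")]] <- likelihood
  tracking_table(df, fps = fps)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# pick a Ward cut threshold inside the merge-height gap that separates the
# C generative clusters (midpoint between the C-th and (C-1)-th largest
# merge heights of the tree)
in_gap_threshold <- function(labels_obj, C) {
  h <- sort(labels_obj$linkage$height, decreasing = TRUE)
  (h[C - 1L] + h[C]) / 2
}
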