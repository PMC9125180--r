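#' Plot a trajectory colored by time
#'
#' Renders the [trajectory_points()] data product; the y axis is reversed so
#' the plot matches the video (image convention, origin top-left).
#'
#' @param t a `tracking_table`.
#' @param bodypart body-part name.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(t, bodypart) {
  d <- trajectory_points(t, bodypart)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$time_s)) +
    ggplot2::geom_path(linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_viridis_c(name = "time (s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("x (", t$units, ")"),
                  y = paste0("y (", t$units, ")"),
                  title = paste("Trajectory:", bodypart)) +
    ggplot2::theme_minimal()
}

#' Plot an occupancy map
#'
#' @param map an `occupancy_map` from [occupancy()].
#' @param vmax optional upper limit of the color scale (counts above it are
#'   clamped), mirroring the usual heatmap `vmax` parameter.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(map, vmax = NULL) {
  xc <- (map$x_edges[-1] + map$x_edges[-length(map$x_edges)]) / 2
  yc <- (map$y_edges[-1] + map$y_edges[-length(map$y_edges)]) / 2
  d <- expand.grid(x = xc, y = yc)
  d$count <- as.vector(map$counts)
  if (!is.null(vmax)) d$count <- pmin(d$count, vmax)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "frames") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Occupancy:", map$bodypart)) +
    ggplot2::theme_minimal()
}

#' Plot interaction events as a timeline
#'
#' Beginning, end and duration of every area visit across the session.
#'
#' @param events an `interaction_events` data.frame.
#' @return A ggplot object.
#' @export
plot_interactions <- function(events) {
  ggplot2::ggplot(events,
                  ggplot2::aes(y = .data$area, yend = .data$area,
                               x = .data$start_s, xend = .data$end_s,
                               color = .data$area)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Area interactions") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' Plot a behavior embedding colored by cluster
#'
#' @param embedding a `tsne_embedding` (or any n x 2 matrix).
#' @param labels a `behavior_labels` object or integer vector.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels) {
  lab <- if (inherits(labels, "behavior_labels")) labels$labels else labels
  d <- data.frame(dim1 = embedding[, 1L], dim2 = embedding[, 2L],
                  cluster = factor(lab))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                  color = .data$cluster)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(title = "Behavior map") +
    ggplot2::theme_minimal()
}

#' Plot the cluster merge dendrogram
#'
#' Base-graphics dendrogram of the Ward merge tree with the cut threshold
#' drawn; cluster proximity in the tree hints at related behaviors.
#'
#' @param labels a `behavior_labels` object from [cluster_frames()].
#' @param ... passed to `plot.hclust`.
#' @return Invisibly, `labels`.
#' @export
plot_dendrogram <- function(labels, ...) {
  stopifnot(inherits(labels, "behavior_labels"))
  plot(labels$hclust, labels = FALSE, hang = -1,
       main = "Behavior cluster dendrogram",
       xlab = "frames", sub = "", ylab = "Ward merge height", ...)
  graphics::abline(h = labels$distance_threshold, lty = 2, col = "red")
  invisible(labels)
}
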