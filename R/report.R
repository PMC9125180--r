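#' Unified multi-animal report
#'
#' One row per animal combining motion metrics and (optionally) per-area
#' interaction summaries — the standard group-level table for comparing
#' treatments or sessions. Each row equals the single-animal operations run
#' independently on that animal's table.
#'
#' @param tables list of `tracking_table`s, one per animal.
#' @param names unique animal names, same length as `tables`.
#' @param bodypart body part used for both metrics and interactions.
#' @param areas optional `area_set`; when given, two columns per area are
#'   added (`<label>_n_interactions`, `<label>_time_s`).
#' @param window optional [time_window()] applied per animal.
#' @return data.frame with columns `name`, `total_distance`, `mean_speed`,
#'   `max_speed`, `units`, `window_start_s`, `window_end_s`, plus the area
#'   columns.
#' @export
build_report <- function(tables, names, bodypart, areas = NULL,
                         window = NULL) {
  if (inherits(tables, "tracking_table")) tables <- list(tables)
  if (length(tables) != length(names))
    stop("`tables` and `names` must have the same length")
  if (anyDuplicated(names)) stop("animal names must be unique")

  rows <- Map(function(t, nm) {
    tw <- if (is.null(window)) t else select_time_window(t, window)
    m <- motion_metrics(tw, bodypart)
    row <- data.frame(
      name = nm,
      total_distance = m$total_distance,
      mean_speed = m$mean_speed,
      max_speed = m$max_speed,
      units = m$units,
      window_start_s = if (is.null(window)) 0 else window$start_s,
      window_end_s = if (is.null(window)) n_frames(t) / t$fps else window$end_s)
    if (!is.null(areas)) {
      ev <- detect_interactions(tw, bodypart, areas)
      sm <- summarize_interactions(ev, areas)
      for (i in seq_len(nrow(sm))) {
        row[[paste0(sm$area[i], "_n_interactions")]] <- sm$n_interactions[i]
        row[[paste0(sm$area[i], "_time_s")]] <- sm$total_time_s[i]
      }
    }
    row
  }, tables, names)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
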