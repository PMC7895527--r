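# ggplot2 visualisations of the result types

#' SuperPlot of per-cell values and replicate means
#'
#' Small jittered dots are technical replicates (cells), large dots the
#' biological-replicate means the statistics run on.
#'
#' @param object a `superplot_table`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.superplot_table <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$condition, y = .data$value,
                               colour = factor(.data$replicate))) +
    ggplot2::geom_jitter(width = 0.18, alpha = 0.45, size = 1.2) +
    ggplot2::geom_point(data = object$replicates,
                        ggplot2::aes(y = .data$mean), size = 4) +
    ggplot2::labs(x = NULL, y = "value", colour = "replicate") +
    ggplot2::theme_minimal()
}

#' Per-step blebbing activity trace
#'
#' @param object a `blebbing_result`.
#' @param ... unused.
#' @return A ggplot of the normalized shape-difference series with the
#'   mean activity as a horizontal line.
#' @export
autoplot.blebbing_result <- function(object, ...) {
  ggplot2::ggplot(object$per_step,
                  ggplot2::aes(x = .data$time_s, y = .data$normalized_diff)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$activity, linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "normalized shape difference",
                  title = sprintf("blebbing activity = %.3f", object$activity)) +
    ggplot2::theme_minimal()
}

#' Escape-record distance and shape dynamics
#'
#' Front/centroid/rear distances to the confinement border over time, with
#' the front- and whole-cell-crossing times marked.
#'
#' @param object an `escape_record`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.escape_record <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_frame,
                            c("front_um", "centroid_um_dist", "rear_um"),
                            names_to = "edge", values_to = "distance_um")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$distance_um,
                                        colour = .data$edge)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "distance to border (µm)") +
    ggplot2::theme_minimal()
  if (!is.na(object$t_front_s)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_front_s, linetype = 3)
  }
  if (!is.na(object$t_complete_s)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_complete_s, linetype = 2)
  }
  p
}

#' Event-aligned elongation/area ribbon plot
#'
#' Mean aspect ratio and projected area across cells, re-zeroed at the
#' event (ribbons: +/- SD) — escaping cells elongate during crossing and
#' relax after.
#'
#' @param aligned output of [align_to_event()].
#' @return A ggplot with two panels (aspect ratio, projected area).
#' @export
plot_aligned_dynamics <- function(aligned) {
  long <- dplyr::bind_rows(
    tibble(rel_time_s = aligned$rel_time_s, metric = "aspect ratio",
           mean = aligned$mean_aspect_ratio, sd = aligned$sd_aspect_ratio),
    tibble(rel_time_s = aligned$rel_time_s, metric = "projected area (µm²)",
           mean = aligned$mean_area_um2, sd = aligned$sd_area_um2))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rel_time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time relative to event (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Linescan profile plot
#'
#' @param object a `linescan_profile`.
#' @param peaks optional output of [detect_peaks()] to mark.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.linescan_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position_um,
                                            y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (µm)", y = "intensity (AU)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(data = peaks, colour = "red", size = 2)
  }
  p
}
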