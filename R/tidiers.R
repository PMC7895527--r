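# broom-style tidiers for the package's result objects

#' Tidy a blebbing result into its per-step series
#'
#' @param x a `blebbing_result`.
#' @param ... unused.
#' @return The per-step tibble (`time_s`, `gained_area_px`,
#'   `lost_area_px`, `area_px`, `normalized_diff`).
#' @export
tidy.blebbing_result <- function(x, ...) x$per_step

#' One-row summary of a blebbing result
#'
#' @param x a `blebbing_result`.
#' @param ... unused.
#' @return A tibble: `track_id`, `activity`, `n_steps`, `normalization`.
#' @export
glance.blebbing_result <- function(x, ...) {
  tibble(track_id = x$track_id, activity = x$activity,
         n_steps = x$n_steps, normalization = x$normalization)
}

#' Tidy an escape record into its per-frame series
#'
#' @param x an `escape_record`.
#' @param ... unused.
#' @return The per-frame tibble (`time_s`, `front_um`, `centroid_um_dist`,
#'   `rear_um`, `frac_outside`, `aspect_ratio`, `area_um2`).
#' @export
tidy.escape_record <- function(x, ...) x$per_frame

#' One-row summary of an escape record
#'
#' @param x an `escape_record`.
#' @param ... unused.
#' @return A tibble: `track_id`, `escaped`, `t_front_s`, `t_complete_s`,
#'   `initial_front_dist_um`, `peak_aspect_ratio`, `mean_angle_deg`.
#' @export
glance.escape_record <- function(x, ...) {
  tibble(track_id = x$track_id, escaped = x$escaped,
         t_front_s = x$t_front_s, t_complete_s = x$t_complete_s,
         initial_front_dist_um = x$initial_front_dist_um,
         peak_aspect_ratio = max(x$per_frame$aspect_ratio),
         mean_angle_deg = if (nrow(x$angles_deg)) mean(x$angles_deg$angle_deg) else NA_real_)
}

#' Tidy a cortex ratio
#'
#' @param x a `cortex_ratio`.
#' @param ... unused.
#' @return A one-row tibble of the ratio and its components.
#' @export
tidy.cortex_ratio <- function(x, ...) {
  tibble(ratio = x$ratio, cortex_mean_AU = x$cortex_mean_AU,
         cytoplasm_mean_AU = x$cytoplasm_mean_AU,
         cortex_band_um = x$cortex_band_um,
         n_cortex_px = x$n_cortex_px, n_cytoplasm_px = x$n_cytoplasm_px)
}

#' Tidy a SuperPlot table into replicate means
#'
#' @param x a `superplot_table`.
#' @param ... unused.
#' @return The replicate-means tibble.
#' @export
tidy.superplot_table <- function(x, ...) x$replicates

#' One-row-per-condition summary of a SuperPlot table
#'
#' @param x a `superplot_table`.
#' @param ... unused.
#' @return A tibble: `condition`, `n_replicates`, `n_cells`,
#'   `mean_of_replicate_means`, `sd_of_replicate_means`.
#' @export
glance.superplot_table <- function(x, ...) {
  x$replicates %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(n_replicates = dplyr::n(),
                     n_cells = sum(.data$n_cells),
                     mean_of_replicate_means = mean(.data$mean),
                     sd_of_replicate_means = ifelse(dplyr::n() > 1, sd(.data$mean), NA_real_),
                     .groups = "drop")
}

#' Tidy a Dunnett test result
#'
#' @param x a `dunnett_test`.
#' @param ... unused.
#' @return The comparisons tibble with a `control` column prepended.
#' @export
tidy.dunnett_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$control <- attr(x, "control")
  out[, c("control", setdiff(names(out), "control"))]
}
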