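#' Simulation parameters
#'
#' Bundles the geometry, kinetics and sampling parameters of the synthetic
#' movie generator. Defaults emulate the imaging conditions and measured
#' scales of confined choanoflagellate movies: 0.1625 µm pixel spacing,
#' ~2.5 µm cell body radius, slow persistent crawling at 0.3 µm/min, and
#' blebs that expand and retract on the minutes scale.
#'
#' @param image_size_px integer pair, frame size in pixels (rows, cols).
#' @param pixel_spacing_um pixel spacing, µm per pixel.
#' @param frame_interval_s interval between frames, s.
#' @param duration_s movie duration, s (frames at `0, dt, ..., <= duration_s`).
#' @param n_cells number of cells.
#' @param body_radius_um cell body radius, µm.
#' @param bleb_rate_per_min bleb nucleation rate per cell, events/min
#'   (Poisson process). May be a vector of length `n_cells` to mix
#'   blebbing and non-blebbing cells.
#' @param bleb_max_radius_um maximum bleb disc radius, µm.
#' @param bleb_expand_s time for a bleb to grow linearly from 0 to its
#'   maximum radius, s.
#' @param bleb_retract_s time for a full-size bleb to shrink back to 0, s.
#' @param migration_speed_um_min crawl speed of the persistent random walk,
#'   µm/min.
#' @param persistence_time_s directional correlation time of the walk, s.
#' @param seed integer master seed; every cell derives a documented
#'   substream seed from it (see Details).
#'
#' @details Per-cell randomness uses substream seeds
#' `(seed mod 1e5) * 10007 + 7919 * cell_id`, so a given cell's trajectory
#' and bleb schedule do not change when `n_cells` changes.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(image_size_px = c(256L, 256L),
                       pixel_spacing_um = 0.1625,
                       frame_interval_s = 5,
                       duration_s = 600,
                       n_cells = 5L,
                       body_radius_um = 2.5,
                       bleb_rate_per_min = 1,
                       bleb_max_radius_um = 1.5,
                       bleb_expand_s = 170,
                       bleb_retract_s = 340,
                       migration_speed_um_min = 0.3,
                       persistence_time_s = 120,
                       seed = 1L) {
  p <- list(image_size_px = as.integer(rep_len(image_size_px, 2L)),
            pixel_spacing_um = pixel_spacing_um,
            frame_interval_s = frame_interval_s,
            duration_s = duration_s,
            n_cells = as.integer(n_cells),
            body_radius_um = body_radius_um,
            bleb_rate_per_min = bleb_rate_per_min,
            bleb_max_radius_um = bleb_max_radius_um,
            bleb_expand_s = bleb_expand_s,
            bleb_retract_s = bleb_retract_s,
            migration_speed_um_min = migration_speed_um_min,
            persistence_time_s = persistence_time_s,
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  assert_scalar_num(p$pixel_spacing_um, "pixel_spacing_um", 0, strict = TRUE)
  assert_scalar_num(p$frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  assert_scalar_num(p$duration_s, "duration_s", 0)
  assert_scalar_num(p$body_radius_um, "body_radius_um", 0, strict = TRUE)
  assert_scalar_num(p$bleb_max_radius_um, "bleb_max_radius_um", 0)
  assert_scalar_num(p$bleb_expand_s, "bleb_expand_s", 0, strict = TRUE)
  assert_scalar_num(p$bleb_retract_s, "bleb_retract_s", 0, strict = TRUE)
  assert_scalar_num(p$migration_speed_um_min, "migration_speed_um_min", 0)
  assert_scalar_num(p$persistence_time_s, "persistence_time_s", 0, strict = TRUE)
  if (p$n_cells < 1L) stop_bleb("`n_cells` must be >= 1")
  if (any(p$bleb_rate_per_min < 0)) stop_bleb("`bleb_rate_per_min` must be >= 0")
  if (!length(p$bleb_rate_per_min) %in% c(1L, p$n_cells)) {
    stop_bleb("`bleb_rate_per_min` must have length 1 or n_cells")
  }
  size_um <- p$image_size_px * p$pixel_spacing_um
  reach <- p$body_radius_um + p$bleb_max_radius_um
  if (any(size_um <= 2 * reach + 1)) {
    stop_bleb("image too small: cells of reach %.2f um cannot stay in a %.1f x %.1f um frame",
              reach, size_um[1], size_um[2])
  }
  invisible(p)
}
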