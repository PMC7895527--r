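# blebbing activity: normalized frame-to-frame shape difference, protrusion
# extraction/classification, phenotype calls

#' Shape difference between two masks of the same cell
#'
#' The regions over which the cell outline differs from the outline one
#' sampling step earlier — the computational signature of blebs. `gained`
#' pixels are present now but absent earlier (expanding protrusions);
#' `lost` pixels were present earlier but are gone now (retracting
#' protrusions).
#'
#' @param mask_now,mask_prev logical matrices (or pixel-index vectors with
#'   a `dim` attribute through `...`) on the same registered grid.
#' @return A list of class `diff_regions`: `gained`, `lost` (sorted linear
#'   pixel indices), `gained_area_px`, `lost_area_px`, `dim`.
#' @export
shape_difference <- function(mask_now, mask_prev) {
  if (!identical(dim(mask_now), dim(mask_prev))) {
    stop_bleb("masks are on different grids (%s vs %s)",
              paste(dim(mask_now), collapse = "x"),
              paste(dim(mask_prev), collapse = "x"))
  }
  now <- px_from_mask(mask_now)
  prev <- px_from_mask(mask_prev)
  gained <- setdiff(now, prev)
  lost <- setdiff(prev, now)
  structure(list(gained = gained, lost = lost,
                 gained_area_px = length(gained),
                 lost_area_px = length(lost),
                 dim = dim(mask_now)),
            class = "diff_regions")
}

# pixel-set variant used internally by track-level code
shape_difference_px <- function(px_now, px_prev, dim) {
  gained <- setdiff(px_now, px_prev)
  lost <- setdiff(px_prev, px_now)
  structure(list(gained = gained, lost = lost,
                 gained_area_px = length(gained),
                 lost_area_px = length(lost),
                 dim = dim),
            class = "diff_regions")
}

#' Blebbing activity of a cell track
#'
#' The core statistic: blebbing activity approximates the rate of cell
#' shape change. For each time point the area of the symmetric difference
#' between the cell shape and the shape one sampling step (20 s) earlier is
#' normalized by the current cell area; the activity is the mean of these
#' per-step values over all time points. A static cell scores 0; a cell
#' continually gaining and losing protrusions scores high. Unitless.
#'
#' Tracks should be QC-filtered, resampled to the 20 s cadence and
#' truncated to the first 240 s before this is meaningful (see
#' [filter_tracks()]).
#'
#' @param track a `cell_tracks` tibble containing exactly one track, or a
#'   multi-track table together with `track_id`.
#' @param track_id which track to analyse when `track` has several.
#' @param normalization `"current"` divides each step's difference area by
#'   the current-frame cell area (default; each step is a local rate);
#'   `"mean"` divides by the track-mean area.
#' @return A list of class `blebbing_result`: `per_step` (tibble with
#'   `time_s`, `gained_area_px`, `lost_area_px`, `area_px`,
#'   `normalized_diff`), `activity` (mean of `normalized_diff`), `n_steps`.
#' @export
blebbing_activity <- function(track, track_id = NULL,
                              normalization = c("current", "mean")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(track, "cell_tracks"))
  if (!is.null(track_id)) track <- subset_tracks(track, track$track_id == track_id)
  if (length(unique(track$track_id)) != 1L) {
    stop_bleb("`track` must contain exactly one track (got %d); pass `track_id`",
              length(unique(track$track_id)))
  }
  if (nrow(track) < 2L) stop_bleb("track has fewer than 2 samples")
  track <- track[order(track$time_s), , drop = FALSE]
  dim <- attr(track, "dim_px")
  n <- nrow(track)
  steps <- lapply(seq_len(n - 1L), function(k) {
    d <- shape_difference_px(track$pixels[[k + 1L]], track$pixels[[k]], dim)
    area_ref <- if (normalization == "current") track$area_px[k + 1L] else mean(track$area_px)
    tibble(time_s = track$time_s[k + 1L],
           gained_area_px = d$gained_area_px,
           lost_area_px = d$lost_area_px,
           area_px = track$area_px[k + 1L],
           normalized_diff = (d$gained_area_px + d$lost_area_px) / area_ref)
  })
  per_step <- dplyr::bind_rows(steps)
  structure(list(per_step = per_step,
                 activity = mean(per_step$normalized_diff),
                 n_steps = n - 1L,
                 track_id = track$track_id[1],
                 normalization = normalization),
            class = "blebbing_result")
}

#' @export
print.blebbing_result <- function(x, ...) {
  cat(sprintf("<blebbing_result> track %s: activity = %.4f over %d steps\n",
              format(x$track_id), x$activity, x$n_steps))
  invisible(x)
}

#' Blebbing activity for every track in a table
#'
#' @param tracks a `cell_tracks` tibble.
#' @inheritParams blebbing_activity
#' @return A tibble with one row per track: `track_id`, `activity`,
#'   `n_steps`.
#' @export
blebbing_activity_all <- function(tracks, normalization = "current") {
  ids <- unique(tracks$track_id)
  dplyr::bind_rows(lapply(ids, function(id) {
    r <- blebbing_activity(tracks, track_id = id, normalization = normalization)
    tibble(track_id = id, activity = r$activity, n_steps = r$n_steps)
  }))
}

#' Extract protrusion events from a shape difference
#'
#' Connected components (8-connectivity) of the gained region become
#' *expanding* protrusion events; components of the lost region become
#' *retracting* events — the automated analogue of classifying blebs as
#' expanding or retracting. Components smaller than `min_protrusion_px`
#' (boundary flicker) are dropped.
#'
#' @param diff a `diff_regions` from [shape_difference()].
#' @param time_s time stamp to attach to the events, s.
#' @param spacing_um pixel spacing, µm/px.
#' @param min_protrusion_px minimum component size in pixels.
#' @return A tibble with one row per event: `time_s`, `class`
#'   (`"expanding"`/`"retracting"`), `area_px`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`, `component_id`, and a `pixels`
#'   list-column.
#' @export
extract_protrusions <- function(diff, time_s = NA_real_, spacing_um = 0.1625,
                                min_protrusion_px = 10L) {
  stopifnot(inherits(diff, "diff_regions"))
  one_side <- function(px, klass) {
    comps <- label_components8(px, diff$dim)
    comps <- comps[lengths(comps) >= min_protrusion_px]
    if (length(comps) == 0L) return(NULL)
    dplyr::bind_rows(lapply(seq_along(comps), function(i) {
      ctr <- px_centroid_um(comps[[i]], diff$dim, spacing_um)
      tibble(time_s = time_s, class = klass,
             area_px = length(comps[[i]]),
             area_um2 = length(comps[[i]]) * spacing_um^2,
             centroid_x_um = ctr[["x"]], centroid_y_um = ctr[["y"]],
             component_id = i, pixels = list(comps[[i]]))
    }))
  }
  out <- dplyr::bind_rows(one_side(diff$gained, "expanding"),
                          one_side(diff$lost, "retracting"))
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(time_s = numeric(0), class = character(0),
                  area_px = integer(0), area_um2 = numeric(0),
                  centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                  component_id = integer(0), pixels = list())
  }
  out
}

#' Protrusion events along a whole track
#'
#' Runs [shape_difference()] + [extract_protrusions()] over every
#' consecutive pair of track samples.
#'
#' @param track a single-track `cell_tracks` tibble.
#' @param min_protrusion_px minimum component size, px.
#' @return The event tibble of [extract_protrusions()] with a `track_id`
#'   column.
#' @export
protrusion_events <- function(track, min_protrusion_px = 10L) {
  stopifnot(inherits(track, "cell_tracks"))
  if (length(unique(track$track_id)) != 1L) stop_bleb("pass a single track")
  track <- track[order(track$time_s), , drop = FALSE]
  dim <- attr(track, "dim_px")
  spacing <- attr(track, "pixel_spacing_um")
  out <- list()
  for (k in seq_len(nrow(track) - 1L)) {
    d <- shape_difference_px(track$pixels[[k + 1L]], track$pixels[[k]], dim)
    ev <- extract_protrusions(d, time_s = track$time_s[k + 1L],
                              spacing_um = spacing,
                              min_protrusion_px = min_protrusion_px)
    if (nrow(ev)) {
      ev$track_id <- track$track_id[1]
      out[[length(out) + 1L]] <- ev
    }
  }
  if (length(out) == 0L) {
    return(tibble(time_s = numeric(0), class = character(0),
                  area_px = integer(0), area_um2 = numeric(0),
                  centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                  component_id = integer(0), pixels = list(),
                  track_id = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Count bleb nucleation onsets along a track by angular novelty
#'
#' Estimates how many distinct blebs nucleated during a track. A growing
#' bleb produces a gained ring at a stable range of boundary angles
#' (measured from the cell centroid) step after step, so a *new* bleb is
#' recognised as gained pixels covering an angular sector that the
#' previous step's gained pixels did not cover. This is robust where
#' pixel-adjacency chaining is not: gained rings of angularly close blebs
#' may merge into one connected component, yet each bleb still contributes
#' its own novel angular run when it first appears.
#'
#' Per step, gained-pixel angles are binned (width `bin_deg`); bins
#' covered in the previous step, dilated by `margin_deg` to absorb the
#' angular widening of a growing bleb, are blocked. Circular runs of novel
#' bins count as one onset each when their angular width lies in
#' `[min_run_deg, max_run_deg]` (very wide thin arcs are translation
#' crescents from cell motion, not blebs) and they contain at least
#' `min_px` gained pixels.
#'
#' @param track a single-track `cell_tracks` tibble (resampled).
#' @param bin_deg angular bin width, degrees.
#' @param margin_deg dilation of the previous step's coverage, degrees.
#' @param min_run_deg,max_run_deg admissible angular width of a novel run.
#' @param min_px minimum gained pixels in a novel run.
#' @param min_component_px minimum gained-component size used to build the
#'   angular coverage (suppresses 1-2 px boundary flicker).
#' @return A tibble with one row per detected onset: `time_s`,
#'   `angle_deg` (run centre), `run_deg`, `n_px`.
#' @export
count_bleb_onsets <- function(track, bin_deg = 2, margin_deg = 6,
                              min_run_deg = 6, max_run_deg = 90,
                              min_px = 5L, min_component_px = 3L) {
  stopifnot(inherits(track, "cell_tracks"))
  if (length(unique(track$track_id)) != 1L) stop_bleb("pass a single track")
  track <- track[order(track$time_s), , drop = FALSE]
  dim <- attr(track, "dim_px")
  nbin <- as.integer(round(360 / bin_deg))
  margin_bins <- as.integer(ceiling(margin_deg / bin_deg))
  prev_cov <- logical(nbin)
  out <- list()
  for (k in seq_len(nrow(track) - 1L)) {
    gained <- setdiff(track$pixels[[k + 1L]], track$pixels[[k]])
    comps <- label_components8(gained, dim)
    comps <- comps[lengths(comps) >= min_component_px]
    gained <- unlist(comps)
    if (length(gained) == 0L) { prev_cov <- logical(nbin); next }
    ctr <- px_rowcol(track$pixels[[k + 1L]], dim)
    cx <- mean(ctr[, "col"]); cy <- mean(ctr[, "row"])
    rc <- px_rowcol(gained, dim)
    ang <- atan2(rc[, "row"] - cy, rc[, "col"] - cx) %% (2 * pi)
    bins <- pmin(floor(ang / (2 * pi) * nbin) + 1L, nbin)
    cov <- tabulate(bins, nbin) > 0
    blocked <- circular_dilate(prev_cov, margin_bins)
    novel <- cov & !blocked
    runs <- circular_runs(novel)
    # runs still below the size minimum must not block themselves: they are
    # kept out of the next step'"'"'s coverage so a slowly growing bleb stays
    # novel until it first qualifies (then it is counted exactly once)
    immature <- logical(length(cov))
    for (r in runs) {
      width <- length(r) * bin_deg
      npx <- sum(bins %in% r)
      if (width > max_run_deg) next # translation crescent: blocks, never counts
      if (width >= min_run_deg && npx >= min_px) {
        mid <- r[ceiling(length(r) / 2)]
        out[[length(out) + 1L]] <- tibble(
          time_s = track$time_s[k + 1L],
          angle_deg = (mid - 0.5) * bin_deg,
          run_deg = width, n_px = npx)
      } else {
        immature[r] <- TRUE
      }
    }
    prev_cov <- cov & !immature
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(time_s = numeric(0), angle_deg = numeric(0),
                  run_deg = numeric(0), n_px = integer(0))
  }
  res
}

circular_dilate <- function(x, by) {
  if (by <= 0 || !any(x)) return(x)
  n <- length(x)
  out <- x
  for (s in seq_len(by)) {
    out <- out | x[((seq_len(n) - 1 + s) %% n) + 1] | x[((seq_len(n) - 1 - s) %% n) + 1]
  }
  out
}

# circularly connected runs of TRUE indices
circular_runs <- function(x) {
  n <- length(x)
  if (!any(x)) return(list())
  if (all(x)) return(list(seq_len(n)))
  # rotate so position 1 is FALSE, then standard rle
  off <- which(!x)[1]
  xs <- x[((seq_len(n) - 1 + off - 1) %% n) + 1]
  r <- rle(xs)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  runs <- lapply(which(r$values), function(i) {
    ((seq(starts[i], ends[i]) - 1 + off - 1) %% n) + 1
  })
  runs
}

#' Classify a cell's phenotype from its blebbing activity
#'
#' Calls a cell *amoeboid* — defined by the presence of dynamic
#' protrusions — when its blebbing activity is at or above
#' `activity_threshold` (inclusive), else *flagellate*. The threshold has
#' no published numeric value (the phenotype was scored by eye); use
#' [calibrate_activity_threshold()] to set it as the 99th percentile of
#' the activity of simulated non-blebbing cells run through the full
#' segmentation pipeline.
#'
#' @param result a `blebbing_result`, or a bare numeric activity value
#'   (vectorised).
#' @param activity_threshold decision threshold (unitless activity).
#' @return `"amoeboid"` or `"flagellate"` (character, vectorised over
#'   numeric input).
#' @export
classify_phenotype <- function(result, activity_threshold) {
  act <- if (inherits(result, "blebbing_result")) result$activity else result
  if (!is.numeric(act)) stop_bleb("`result` must be a blebbing_result or numeric")
  ifelse(act >= activity_threshold, "amoeboid", "flagellate")
}

#' Calibrate the amoeboid/flagellate activity threshold on simulations
#'
#' Simulates non-blebbing (flagellate) cells, renders them as noisy
#' cortical-fluorescence movies, runs the full segmentation + tracking +
#' activity pipeline, and returns the 99th percentile of the resulting
#' activity values. Segmentation noise gives non-blebbing cells a small
#' positive activity; the 99th percentile bounds the false-amoeboid rate
#' at ~1% by construction.
#'
#' @param n_cells number of simulated flagellate cells (across movies).
#' @param noise_sd render noise (fraction of baseline).
#' @param seed integer seed.
#' @param cells_per_movie cells per simulated movie.
#' @return The calibrated threshold (scalar). The activity sample is
#'   attached as attribute `"activities"`.
#' @export
calibrate_activity_threshold <- function(n_cells = 40L, noise_sd = 0.05,
                                         seed = 99L, cells_per_movie = 10L) {
  n_movies <- ceiling(n_cells / cells_per_movie)
  acts <- numeric(0)
  for (m in seq_len(n_movies)) {
    p <- sim_params(image_size_px = c(448L, 448L), frame_interval_s = 20,
                    duration_s = 240, n_cells = cells_per_movie,
                    bleb_rate_per_min = 0, migration_speed_um_min = 0.3,
                    seed = seed + m)
    sim <- simulate_blebbing_movie(p)
    fluo <- render_intensity_movie(sim$movie, mode = "cortex_fluor",
                                   noise_sd = noise_sd, seed = seed + m,
                                   ground_truth = sim$ground_truth)
    labs <- segment_movie(fluo, min_object_px = 200L)
    tracks <- link_tracks(labs, max_link_dist_px = 10)
    act <- blebbing_activity_all(tracks)
    act <- act[act$n_steps >= 10, , drop = FALSE] # full-length tracks only
    acts <- c(acts, act$activity)
  }
  thr <- as.numeric(quantile(acts, 0.99, names = FALSE, type = 7))
  attr(thr, "activities") <- acts
  thr
}
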