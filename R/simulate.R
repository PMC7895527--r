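# synthetic movie generator: blebbing cells, escape assays, fluorescence renders

# pixels whose centers fall inside a disc; pixel center (row, col) sits at
# physical ((col-1)*s, (row-1)*s)
disc_px <- function(center_um, radius_um, spacing_um, dim) {
  if (radius_um <= 0) return(integer(0))
  cx <- center_um[1]; cy <- center_um[2]; s <- spacing_um
  r1 <- max(1L, floor((cy - radius_um) / s) + 1L)
  r2 <- min(dim[1], ceiling((cy + radius_um) / s) + 1L)
  c1 <- max(1L, floor((cx - radius_um) / s) + 1L)
  c2 <- min(dim[2], ceiling((cx + radius_um) / s) + 1L)
  if (r1 > r2 || c1 > c2) return(integer(0))
  rows <- r1:r2
  cols <- c1:c2
  px <- (cols[1] - 1) * s + (seq_along(cols) - 1) * s
  py <- (rows[1] - 1) * s + (seq_along(rows) - 1) * s
  inside <- outer((py - cy)^2, (px - cx)^2, `+`) <= radius_um^2
  idx <- which(inside)
  if (length(idx) == 0L) return(integer(0))
  r <- rows[((idx - 1L) %% length(rows)) + 1L]
  cc <- cols[((idx - 1L) %/% length(rows)) + 1L]
  sort((cc - 1L) * dim[1] + r)
}

# axis-aligned-in-rotated-frame ellipse; theta = major-axis direction (rad)
ellipse_px <- function(center_um, a_um, b_um, theta, spacing_um, dim) {
  if (a_um <= 0 || b_um <= 0) return(integer(0))
  cx <- center_um[1]; cy <- center_um[2]; s <- spacing_um
  r0 <- max(a_um, b_um)
  r1 <- max(1L, floor((cy - r0) / s) + 1L)
  r2 <- min(dim[1], ceiling((cy + r0) / s) + 1L)
  c1 <- max(1L, floor((cx - r0) / s) + 1L)
  c2 <- min(dim[2], ceiling((cx + r0) / s) + 1L)
  if (r1 > r2 || c1 > c2) return(integer(0))
  rows <- r1:r2
  cols <- c1:c2
  grid <- expand.grid(row = rows, col = cols)
  dx <- (grid$col - 1) * s - cx
  dy <- (grid$row - 1) * s - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a_um
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_um
  keep <- u^2 + v^2 <= 1
  sort((grid$col[keep] - 1L) * dim[1] + grid$row[keep])
}

# triangular bleb radius profile: linear growth then linear retraction
bleb_radius_at <- function(t, t0, rmax, expand_s, retract_s) {
  dt <- t - t0
  r <- ifelse(dt < 0, 0,
       ifelse(dt <= expand_s, rmax * dt / expand_s,
       ifelse(dt <= expand_s + retract_s,
              rmax * (1 - (dt - expand_s) / retract_s), 0)))
  pmax(r, 0)
}

# area of a bleb disc (radius r, center at distance d from body center)
# lying outside the body disc (radius R); closed-form circle lens
bleb_area_outside <- function(r, R, d) {
  if (r <= 0) return(0)
  if (d >= r + R) return(pi * r^2)
  if (d + r <= R) return(0)
  lens <- r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r)) +
    R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R)) -
    0.5 * sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R))
  pi * r^2 - lens
}

# persistent random walk with reflecting walls; returns positions (um) at
# the given times plus the realized headings
sim_walk <- function(start_um, times, speed_um_min, persistence_time_s,
                     lo_um, hi_um) {
  n <- length(times)
  pos <- matrix(0, n, 2)
  pos[1, ] <- start_um
  theta <- runif(1, 0, 2 * pi)
  v <- speed_um_min / 60
  for (k in seq_len(n - 1)) {
    dt <- times[k + 1] - times[k]
    theta <- theta + rnorm(1, 0, sqrt(2 * dt / persistence_time_s))
    p <- pos[k, ] + v * dt * c(cos(theta), sin(theta))
    if (p[1] < lo_um[1]) { p[1] <- 2 * lo_um[1] - p[1]; theta <- pi - theta }
    if (p[1] > hi_um[1]) { p[1] <- 2 * hi_um[1] - p[1]; theta <- pi - theta }
    if (p[2] < lo_um[2]) { p[2] <- 2 * lo_um[2] - p[2]; theta <- -theta }
    if (p[2] > hi_um[2]) { p[2] <- 2 * hi_um[2] - p[2]; theta <- -theta }
    pos[k + 1, ] <- p
  }
  pos
}

place_cells <- function(n, lo_um, hi_um, min_sep_um, max_attempts = 200L * n) {
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (attempt in seq_len(max_attempts)) {
    cand <- c(runif(1, lo_um[1], hi_um[1]), runif(1, lo_um[2], hi_um[2]))
    ok <- placed == 0L ||
      all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2)) >= min_sep_um)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop_bleb("could not place %d non-overlapping cells after %d attempts; enlarge the frame or reduce n_cells",
            n, max_attempts)
}

#' Simulate a label movie of blebbing cells with ground truth
#'
#' Each cell is a disc body that crawls as a persistent random walk and
#' stochastically nucleates blebs: discs anchored at a fixed angle on the
#' body boundary that grow linearly to `bleb_max_radius_um` over
#' `bleb_expand_s`, then shrink back to zero over `bleb_retract_s`
#' (the minutes-scale expand/retract cycle seen in confined blebbing cells).
#' Nucleation is a per-cell Poisson process at `bleb_rate_per_min`; anchor
#' angles are uniform on `[0, 2*pi)`. Shapes are rasterized as unions of
#' discs with pixel-center membership. Cells are placed with enough initial
#' separation that they can never overlap given the programmed speed and
#' duration, and walls reflect so no cell leaves the frame.
#'
#' @param params a [sim_params()] object.
#' @return A list with elements `movie` (a label [movie_stack()]) and
#'   `ground_truth`: true centroid tracks (µm), the bleb event log
#'   (cell id, nucleation time, anchor angle, maximum protruding area in
#'   µm²), per-cell phenotype labels (`"amoeboid"` iff that cell's bleb
#'   rate is positive, else `"flagellate"`), and the generating parameters.
#'   Identical seeds give bit-identical output.
#' @export
#' @examples
#' sim <- simulate_blebbing_movie(sim_params(n_cells = 2, duration_s = 60))
#' sim$movie
#' sim$ground_truth$bleb_events
simulate_blebbing_movie <- function(params = sim_params()) {
  validate_sim_params(params)
  p <- params
  dim <- p$image_size_px
  s <- p$pixel_spacing_um
  size_um <- dim * s
  times <- seq(0, p$duration_s, by = p$frame_interval_s)
  reach <- p$body_radius_um + p$bleb_max_radius_um
  drift <- p$migration_speed_um_min / 60 * p$duration_s
  lo <- c(reach + s, reach + s)
  hi <- c(size_um[2] - reach - s, size_um[1] - reach - s) # (x, y)
  if (any(hi <= lo)) stop_bleb("image too small for the programmed cell reach")
  rates <- rep_len(p$bleb_rate_per_min, p$n_cells)

  centers <- with_seed(p$seed,
    place_cells(p$n_cells, lo, hi, min_sep_um = 2 * reach + 2 * drift + 0.5))

  tracks <- vector("list", p$n_cells)
  events <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    with_seed(cell_subseed(p$seed, i), {
      pos <- sim_walk(centers[i, ], times, p$migration_speed_um_min,
                      p$persistence_time_s, lo, hi)
      ev <- if (rates[i] > 0) {
        t <- 0; out <- numeric(0)
        repeat {
          t <- t + rexp(1, rate = rates[i] / 60)
          if (t > p$duration_s) break
          out <- c(out, t)
        }
        tibble(cell_id = i, time_s = out,
               angle_rad = runif(length(out), 0, 2 * pi))
      } else {
        tibble(cell_id = integer(0), time_s = numeric(0), angle_rad = numeric(0))
      }
    })
    tracks[[i]] <- tibble(cell_id = i, time_s = times,
                          x_um = pos[, 1], y_um = pos[, 2])
    events[[i]] <- ev
  }
  true_tracks <- dplyr::bind_rows(tracks)
  bleb_events <- dplyr::bind_rows(events)
  if (nrow(bleb_events)) {
    bleb_events$max_area_um2 <- vapply(seq_len(nrow(bleb_events)), function(k) {
      bleb_area_outside(p$bleb_max_radius_um, p$body_radius_um, p$body_radius_um)
    }, numeric(1))
  } else {
    bleb_events$max_area_um2 <- numeric(0)
  }

  frames <- rasterize_frames(true_tracks, bleb_events, times, p)
  gt <- structure(
    list(true_tracks = true_tracks,
         bleb_events = bleb_events,
         phenotypes = tibble(cell_id = seq_len(p$n_cells),
                             phenotype = ifelse(rates > 0, "amoeboid", "flagellate")),
         escape = NULL, boundary = NULL, fluor_ratio_true = NULL,
         params = unclass(p)),
    class = "ground_truth")
  list(movie = movie_stack(frames, s, p$frame_interval_s, kind = "label",
                           timestamps_s = times),
       ground_truth = gt)
}

# shared frame rasterizer: body disc (or ellipse when ar columns present)
# plus active bleb discs, one label per cell
rasterize_frames <- function(true_tracks, bleb_events, times, p) {
  dim <- p$image_size_px
  s <- p$pixel_spacing_um
  has_ar <- "aspect_ratio" %in% names(true_tracks)
  lapply(seq_along(times), function(k) {
    t <- times[k]
    lab <- matrix(0L, dim[1], dim[2])
    rows_t <- true_tracks[true_tracks$time_s == t, ]
    for (j in seq_len(nrow(rows_t))) {
      id <- rows_t$cell_id[j]
      ctr <- c(rows_t$x_um[j], rows_t$y_um[j])
      if (has_ar && rows_t$aspect_ratio[j] > 1) {
        ar <- rows_t$aspect_ratio[j]
        px <- ellipse_px(ctr, p$body_radius_um * sqrt(ar),
                         p$body_radius_um / sqrt(ar),
                         rows_t$orientation_rad[j], s, dim)
      } else {
        px <- disc_px(ctr, p$body_radius_um, s, dim)
      }
      ev <- bleb_events[bleb_events$cell_id == id, ]
      if (nrow(ev)) {
        rb <- bleb_radius_at(t, ev$time_s, p$bleb_max_radius_um,
                             p$bleb_expand_s, p$bleb_retract_s)
        for (m in which(rb > 0)) {
          anchor <- ctr + p$body_radius_um *
            c(cos(ev$angle_rad[m]), sin(ev$angle_rad[m]))
          px <- union(px, disc_px(anchor, rb[m], s, dim))
        }
      }
      if (any(lab[px] != 0L)) {
        stop_bleb("internal error: overlapping cells at t = %g s", t)
      }
      lab[px] <- id
    }
    lab
  })
}

#' Simulate a confinement escape-assay movie
#'
#' A single confined cell starts `start_dist_um` inside a circular
#' confinement boundary, blebs in place for `bleb_phase_s`, then crawls
#' radially outward (the shortest escape path) at `crawl_speed_um_min`.
#' While crossing the border the programmed aspect ratio ramps from 1 up to
#' `ar_peak` (> 1.5) and relaxes back to 1 once the whole cell is outside,
#' with the body deforming area-preservingly into an ellipse aligned with
#' the escape direction. Ground truth records the programmed path, the
#' per-frame aspect ratio, and the front-crossing / rear-crossing times.
#'
#' @param params a [sim_params()]; `n_cells` is forced to 1.
#' @param boundary a [confinement_boundary()], or `NULL` for a circle
#'   centred in the frame with radius 0.3 of the smaller frame dimension
#'   (leaving unconfined space inside the frame to escape into).
#' @param start_dist_um initial distance of the cell centre from the border
#'   (µm, inside); must not exceed the boundary radius.
#' @param bleb_phase_s duration of the stationary blebbing phase, s.
#' @param crawl_speed_um_min radial crawl speed after the blebbing phase.
#' @param ar_peak peak programmed aspect ratio during crossing.
#' @param relax_s time to relax back to a round shape after the rear
#'   crosses, s.
#' @return As [simulate_blebbing_movie()]; `ground_truth$escape` holds
#'   `t_front_s` / `t_complete_s` (NA when no crossing is programmed) and
#'   `ground_truth$boundary` the circle.
#' @export
simulate_escape_movie <- function(params = sim_params(image_size_px = c(320L, 320L),
                                                      frame_interval_s = 20,
                                                      duration_s = 600,
                                                      n_cells = 1L,
                                                      bleb_rate_per_min = 2,
                                                      bleb_expand_s = 60,
                                                      bleb_retract_s = 60),
                                  boundary = NULL,
                                  start_dist_um = 3,
                                  bleb_phase_s = 180,
                                  crawl_speed_um_min = 1.5,
                                  ar_peak = 1.8,
                                  relax_s = 60) {
  p <- params
  p$n_cells <- 1L
  validate_sim_params(p)
  dim <- p$image_size_px
  s <- p$pixel_spacing_um
  size_um <- dim * s
  if (is.null(boundary)) {
    boundary <- confinement_boundary(center_um = size_um[c(2, 1)] / 2,
                                     radius_um = 0.3 * min(size_um))
  }
  if (start_dist_um > boundary$radius_um) {
    stop_bleb("start_dist_um (%.2f) exceeds the boundary radius (%.2f): cell would not be confined",
              start_dist_um, boundary$radius_um)
  }
  times <- seq(0, p$duration_s, by = p$frame_interval_s)
  R <- p$body_radius_um
  Rb <- boundary$radius_um
  v <- crawl_speed_um_min / 60
  # radial distance of the centre from the boundary centre over time
  d0 <- Rb - start_dist_um
  cdist <- ifelse(times <= bleb_phase_s, d0, d0 + v * (times - bleb_phase_s))
  # keep the cell inside the frame: freeze motion at the wall margin
  reach <- R + p$bleb_max_radius_um
  max_c <- min(size_um) / 2 - reach - s
  cdist <- pmin(cdist, max_c)

  # programmed elongation ramp tied to the round-cell crossing window
  t_front0 <- if (d0 + R >= Rb) 0 else
    if (max(cdist) + R < Rb) NA_real_ else
      bleb_phase_s + (Rb - R - d0) / v
  t_rear0 <- if (max(cdist) - R < Rb) NA_real_ else bleb_phase_s + (Rb + R - d0) / v
  ar_t <- rep(1, length(times))
  if (!is.na(t_front0) && !is.na(t_rear0)) {
    t_mid <- (t_front0 + t_rear0) / 2
    ramp_pre <- max(t_front0 - 40, 0)
    up <- times >= ramp_pre & times <= t_mid
    ar_t[up] <- 1 + (ar_peak - 1) * (times[up] - ramp_pre) / max(t_mid - ramp_pre, 1e-9)
    down <- times > t_mid & times <= t_rear0 + relax_s
    ar_t[down] <- ar_peak - (ar_peak - 1) * (times[down] - t_mid) / max(t_rear0 + relax_s - t_mid, 1e-9)
  }

  ctr_x <- boundary$center_um[1] + cdist
  ctr_y <- rep(boundary$center_um[2], length(times))
  true_tracks <- tibble(cell_id = 1L, time_s = times, x_um = ctr_x, y_um = ctr_y,
                        aspect_ratio = ar_t,
                        orientation_rad = 0)

  # blebs nucleate only early enough to complete their expand/retract cycle
  # before crawling starts, so the crossing geometry is purely the
  # programmed ellipse
  nucleation_end <- max(0, bleb_phase_s - p$bleb_expand_s - p$bleb_retract_s)
  bleb_events <- with_seed(p$seed, {
    rate <- rep_len(p$bleb_rate_per_min, 1L)
    if (rate > 0) {
      t <- 0; out <- numeric(0)
      repeat {
        t <- t + rexp(1, rate = rate / 60)
        if (t > nucleation_end) break
        out <- c(out, t)
      }
      tibble(cell_id = 1L, time_s = out,
             angle_rad = runif(length(out), 0, 2 * pi),
             max_area_um2 = rep(bleb_area_outside(p$bleb_max_radius_um, R, R),
                                length(out)))
    } else {
      tibble(cell_id = integer(0), time_s = numeric(0), angle_rad = numeric(0),
             max_area_um2 = numeric(0))
    }
  })

  # ground-truth crossing times from the analytic radial extents of the
  # body ellipse and any active bleb discs, read on the frame grid
  a_t <- R * sqrt(ar_t)
  ext_max <- cdist + a_t
  ext_min <- cdist - a_t
  if (nrow(bleb_events)) {
    for (k in seq_along(times)) {
      rb <- bleb_radius_at(times[k], bleb_events$time_s, p$bleb_max_radius_um,
                           p$bleb_expand_s, p$bleb_retract_s)
      act <- which(rb > 0)
      if (length(act)) {
        anchor_x <- ctr_x[k] + R * cos(bleb_events$angle_rad[act])
        anchor_y <- ctr_y[k] + R * sin(bleb_events$angle_rad[act])
        da <- sqrt((anchor_x - boundary$center_um[1])^2 +
                     (anchor_y - boundary$center_um[2])^2)
        ext_max[k] <- max(ext_max[k], da + rb[act])
        ext_min[k] <- min(ext_min[k], da - rb[act])
      }
    }
  }
  front_out <- ext_max > Rb
  rear_out <- ext_min > Rb
  t_front <- if (any(front_out)) times[which(front_out)[1]] else NA_real_
  t_complete <- if (any(rear_out)) times[which(rear_out)[1]] else NA_real_

  frames <- rasterize_frames(true_tracks, bleb_events, times, p)
  gt <- structure(
    list(true_tracks = true_tracks,
         bleb_events = bleb_events,
         phenotypes = tibble(cell_id = 1L, phenotype = "amoeboid"),
         escape = tibble(cell_id = 1L,
                         escaped = !is.na(t_complete),
                         t_front_s = t_front,
                         t_complete_s = t_complete,
                         start_dist_um = start_dist_um),
         boundary = boundary, fluor_ratio_true = NULL,
         params = unclass(p)),
    class = "ground_truth")
  list(movie = movie_stack(frames, s, p$frame_interval_s, kind = "label",
                           timestamps_s = times),
       ground_truth = gt)
}

#' Render an intensity movie from a label movie
#'
#' Two render modes. `"cortex_fluor"` emulates a cortical-marker channel
#' (F-actin or myosin II reporter): the cytoplasm is painted at `baseline`
#' intensity and a cortical band of width `cortex_width_um` along the cell
#' boundary at `cortex_to_cytoplasm_ratio` times baseline — except on
#' boundary segments belonging to currently *expanding* blebs, which are
#' cytoplasm-filled but cortex-free. `"dic_like"` produces a flat
#' transmitted-light look (bright background, darker cell, dark rim) good
#' enough to exercise intensity-based segmentation. Gaussian noise with
#' standard deviation `noise_sd * baseline` is added; output is
#' deterministic for a given `seed`.
#'
#' @param labels a label [movie_stack()].
#' @param mode `"cortex_fluor"` or `"dic_like"`.
#' @param cortex_width_um width of the cortical band, µm; must be smaller
#'   than the cell radius.
#' @param cortex_to_cytoplasm_ratio cortical over cytoplasmic mean
#'   intensity of the render (> 0).
#' @param noise_sd Gaussian noise SD as a fraction of `baseline`.
#' @param seed integer seed for the noise.
#' @param ground_truth optional `ground_truth` from the simulator; when
#'   supplied, expanding-bleb regions are excluded from the cortex band
#'   exactly (from the event log); otherwise a frame-difference heuristic
#'   (newly gained pixels, dilated) is used.
#' @param baseline cytoplasm intensity in arbitrary units.
#' @return An intensity [movie_stack()].
#' @export
render_intensity_movie <- function(labels,
                                   mode = c("cortex_fluor", "dic_like"),
                                   cortex_width_um = 0.5,
                                   cortex_to_cytoplasm_ratio = 2,
                                   noise_sd = 0.05,
                                   seed = 1L,
                                   ground_truth = NULL,
                                   baseline = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(labels, "movie_stack"))
  if (labels$kind != "label") stop_bleb("`labels` must be a label movie")
  if (cortex_to_cytoplasm_ratio <= 0) stop_bleb("`cortex_to_cytoplasm_ratio` must be > 0")
  s <- labels$pixel_spacing_um
  width_px <- cortex_width_um / s
  dim <- frame_dim(labels)
  p <- if (!is.null(ground_truth)) ground_truth$params else NULL

  frames <- lapply(seq_along(labels$frames), function(k) {
    lab <- labels$frames[[k]]
    img <- matrix(0, dim[1], dim[2])
    bw <- lab != 0L
    if (!any(bw)) return(img)
    if (mode == "dic_like") {
      img[] <- 0.55 * baseline
      img[bw] <- 0.45 * baseline
      dm <- EBImage::distmap(EBImage::Image(bw * 1))
      rim <- bw & as.matrix(dm) <= 1.5
      img[rim] <- 0.25 * baseline
      return(img)
    }
    img[bw] <- baseline
    dm <- as.matrix(EBImage::distmap(EBImage::Image(bw * 1)))
    for (id in setdiff(unique(as.vector(lab)), 0L)) {
      cell <- lab == id
      if (cortex_width_um >= max(dm[cell]) * s) {
        stop_bleb("cortex_width_um (%.2f um) is not smaller than the cell radius", cortex_width_um)
      }
    }
    band <- bw & dm <= width_px
    img[band] <- cortex_to_cytoplasm_ratio * baseline
    # expanding blebs carry no cortex band
    if (!is.null(p)) {
      t <- labels$timestamps_s[k]
      ev <- ground_truth$bleb_events
      if (nrow(ev)) {
        expanding <- which(t >= ev$time_s & t < ev$time_s + p$bleb_expand_s)
        for (m in expanding) {
          id <- ev$cell_id[m]
          ctr_row <- ground_truth$true_tracks[
            ground_truth$true_tracks$cell_id == id &
              ground_truth$true_tracks$time_s == t, ]
          if (nrow(ctr_row) == 0) next
          rb <- bleb_radius_at(t, ev$time_s[m], p$bleb_max_radius_um,
                               p$bleb_expand_s, p$bleb_retract_s)
          anchor <- c(ctr_row$x_um[1], ctr_row$y_um[1]) +
            p$body_radius_um * c(cos(ev$angle_rad[m]), sin(ev$angle_rad[m]))
          px <- disc_px(anchor, rb, s, dim)
          px <- px[band[px]]
          img[px] <- baseline
        }
      }
    } else if (k > 1L) {
      gained <- bw & labels$frames[[k - 1L]] == 0L
      if (any(gained)) {
        kern <- EBImage::makeBrush(2L * ceiling(width_px) + 1L, shape = "disc")
        grown <- as.matrix(EBImage::dilate(EBImage::Image(gained * 1), kern)) > 0
        img[band & grown] <- baseline
      }
    }
    img
  })
  if (noise_sd > 0) {
    frames <- with_seed(seed, lapply(frames, function(f) {
      pmax(f + rnorm(length(f), 0, noise_sd * baseline), 0)
    }))
  }
  movie_stack(frames, s, labels$frame_interval_s, kind = "intensity",
              timestamps_s = labels$timestamps_s)
}
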