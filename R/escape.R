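# confinement escape-assay geometry: boundary distances, escape detection,
# escape angles, speed/persistence, event-aligned morphodynamics

#' Circular confinement boundary
#'
#' The confinement zone (e.g. a micropillar border) drawn as a circle; the
#' confined side is the interior.
#'
#' @param center_um circle centre `(x, y)` in µm.
#' @param radius_um circle radius in µm (> 0).
#' @return A list of class `confinement_boundary`.
#' @export
confinement_boundary <- function(center_um, radius_um) {
  assert_scalar_num(radius_um, "radius_um", 0, strict = TRUE)
  if (length(center_um) != 2L || !is.numeric(center_um)) {
    stop_bleb("`center_um` must be an (x, y) pair")
  }
  structure(list(center_um = as.numeric(center_um), radius_um = radius_um),
            class = "confinement_boundary")
}

#' Distances between a cell and the confinement border
#'
#' For every cell pixel center `p`, the unsigned distance to the circle is
#' `| ||p - center|| - radius |`. The cell *front* is the minimal such
#' distance over all points within the cell, the *rear* the maximal; the
#' centroid distance is the same quantity evaluated at the centroid.
#'
#' @param mask logical mask, or integer pixel indices when `dim` is given.
#' @param boundary a [confinement_boundary()].
#' @param spacing_um pixel spacing, µm/px.
#' @param dim frame dimensions when `mask` is an index vector.
#' @return A one-row tibble: `front_um`, `centroid_um_dist`, `rear_um`,
#'   plus `frac_outside` (fraction of cell pixels strictly outside the
#'   circle, the signed side used for escape detection).
#' @export
boundary_distances <- function(mask, boundary, spacing_um = 0.1625, dim = NULL) {
  stopifnot(inherits(boundary, "confinement_boundary"))
  if (is.matrix(mask)) {
    px <- px_from_mask(mask)
    dim <- dim(mask)
  } else {
    px <- mask
    if (is.null(dim)) stop_bleb("`dim` required when `mask` is an index vector")
  }
  if (length(px) == 0L) stop_bleb("empty mask")
  rc <- px_rowcol(px, dim)
  x <- (rc[, "col"] - 1) * spacing_um
  y <- (rc[, "row"] - 1) * spacing_um
  r <- sqrt((x - boundary$center_um[1])^2 + (y - boundary$center_um[2])^2)
  d <- abs(r - boundary$radius_um)
  ctr <- c(mean(x), mean(y))
  rc_d <- sqrt(sum((ctr - boundary$center_um)^2))
  tibble(front_um = min(d),
         centroid_um_dist = abs(rc_d - boundary$radius_um),
         rear_um = max(d),
         frac_outside = mean(r > boundary$radius_um))
}

#' Detect escape of a tracked cell from a confinement circle
#'
#' `t_front_s` is the first time any cell pixel lies strictly outside the
#' circle (the first protrusion across the border); `t_complete_s` the
#' first time *all* pixels are outside (whole-cell crossing, the sharpest
#' computable proxy for completed escape). The cell must start confined
#' (initial centroid inside the circle). Whether published escape
#' criteria meant front- or whole-cell crossing is ambiguous, so both
#' times are reported.
#'
#' @param track a single-track `cell_tracks` tibble (pass `track_id` to
#'   select from a multi-track table).
#' @param boundary a [confinement_boundary()].
#' @param track_id optional track selector.
#' @return A list of class `escape_record`: `per_frame` (tibble with
#'   `time_s`, `front_um`, `centroid_um_dist`, `rear_um`, `frac_outside`,
#'   `aspect_ratio`, `area_um2`), `escaped`, `t_front_s`, `t_complete_s`
#'   (NA when absent), `initial_front_dist_um`, `angles_deg` (the
#'   [escape_angle_series()] tibble), `track_id`.
#' @export
detect_escape <- function(track, boundary, track_id = NULL) {
  stopifnot(inherits(track, "cell_tracks"), inherits(boundary, "confinement_boundary"))
  if (!is.null(track_id)) track <- subset_tracks(track, track$track_id == track_id)
  if (length(unique(track$track_id)) != 1L) stop_bleb("pass a single track")
  track <- track[order(track$time_s), , drop = FALSE]
  dim <- attr(track, "dim_px")
  spacing <- attr(track, "pixel_spacing_um")
  if (!"aspect_ratio" %in% names(track)) track <- add_shape_descriptors(track)
  # confinement check on the signed side of the first centroid
  c0 <- c(track$x_um[1], track$y_um[1])
  if (sqrt(sum((c0 - boundary$center_um)^2)) > boundary$radius_um) {
    stop_bleb("initial centroid lies outside the boundary: cell is not confined")
  }
  dists <- dplyr::bind_rows(lapply(seq_len(nrow(track)), function(k) {
    boundary_distances(track$pixels[[k]], boundary, spacing, dim)
  }))
  per_frame <- dplyr::bind_cols(
    tibble(time_s = track$time_s), dists,
    tibble(aspect_ratio = track$aspect_ratio, area_um2 = track$area_um2))
  t_front <- per_frame$time_s[per_frame$frac_outside > 0][1]
  t_complete <- per_frame$time_s[per_frame$frac_outside == 1][1]
  angles <- escape_angle_series(track, boundary)
  structure(list(per_frame = per_frame,
                 escaped = !is.na(t_complete),
                 t_front_s = t_front,
                 t_complete_s = t_complete,
                 initial_front_dist_um = per_frame$front_um[1],
                 angles_deg = angles,
                 track_id = track$track_id[1]),
            class = "escape_record")
}

#' @export
print.escape_record <- function(x, ...) {
  cat(sprintf("<escape_record> track %s: %s (t_front = %s s, t_complete = %s s)\n",
              format(x$track_id),
              if (x$escaped) "escaped" else "did not escape",
              format(x$t_front_s), format(x$t_complete_s)))
  invisible(x)
}

#' Angular deviation of crawling from the shortest escape path
#'
#' For each step, the angle (degrees, in `[0, 180]`) between the centroid
#' displacement and the outward radial direction — the shortest possible
#' escape path from a circular confinement zone. Steps with displacement
#' below `min_step_px` pixels are skipped, as is any step starting exactly
#' at the circle centre (radial direction undefined).
#'
#' @param track a single-track `cell_tracks` tibble with `x_um` / `y_um`.
#' @param boundary a [confinement_boundary()].
#' @param min_step_px minimum displacement for a step to count, px.
#' @return A tibble: `time_s` (step start), `angle_deg`, `displacement_um`.
#' @export
escape_angle_series <- function(track, boundary, min_step_px = 0.5) {
  stopifnot(inherits(boundary, "confinement_boundary"))
  spacing <- attr(track, "pixel_spacing_um") %||% 1
  track <- track[order(track$time_s), , drop = FALSE]
  n <- nrow(track)
  if (n < 2L) {
    return(tibble(time_s = numeric(0), angle_deg = numeric(0),
                  displacement_um = numeric(0)))
  }
  out <- lapply(seq_len(n - 1L), function(k) {
    p0 <- c(track$x_um[k], track$y_um[k])
    p1 <- c(track$x_um[k + 1L], track$y_um[k + 1L])
    disp <- p1 - p0
    dlen <- sqrt(sum(disp^2))
    if (dlen < min_step_px * spacing) return(NULL)
    radial <- p0 - boundary$center_um
    rlen <- sqrt(sum(radial^2))
    if (rlen == 0) {
      message(sprintf("step at t = %g s starts at the circle centre; skipped", track$time_s[k]))
      return(NULL)
    }
    cosang <- sum(disp * radial) / (dlen * rlen)
    tibble(time_s = track$time_s[k],
           angle_deg = acos(pmin(pmax(cosang, -1), 1)) * 180 / pi,
           displacement_um = dlen)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(time_s = numeric(0), angle_deg = numeric(0),
                  displacement_um = numeric(0))
  }
  res
}

#' Speed and directional persistence over sliding windows
#'
#' Over every 2-min window sliding by one resampled frame: speed is the
#' total path length divided by the window duration (µm/min); directional
#' persistence is the ratio of the total path to the Euclidean (net)
#' displacement in the published, `"paper_literal"`, definition — a
#' straightness penalty that is >= 1, larger for more tortuous paths. The
#' `"conventional"` definition is its exact reciprocal
#' (Euclidean / total path, in `[0, 1]`, larger = straighter). Windows
#' with zero net displacement have undefined persistence (NA, with a
#' message).
#'
#' @param track a `cell_tracks` tibble (single track) or any tibble with
#'   `time_s`, `x_um`, `y_um`.
#' @param window_s window length, s.
#' @param definition `"paper_literal"` (total/Euclidean) or
#'   `"conventional"` (Euclidean/total).
#' @return A tibble of class `motility_record`: `time_s` (window start),
#'   `speed_um_min`, `persistence`.
#' @export
speed_and_persistence <- function(track, window_s = 120,
                                  definition = c("paper_literal", "conventional")) {
  definition <- match.arg(definition)
  stopifnot(all(c("time_s", "x_um", "y_um") %in% names(track)))
  track <- track[order(track$time_s), , drop = FALSE]
  t <- track$time_s
  if (diff(range(t)) < window_s) stop_bleb("track shorter than the window (%g s)", window_s)
  dt <- diff(t)
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  starts <- which(t + window_s <= max(t) + 1e-9)
  out <- lapply(starts, function(i) {
    j <- which(abs(t - (t[i] + window_s)) < 1e-9)
    if (length(j) == 0L) return(NULL)
    path <- sum(steps[i:(j - 1L)])
    eucl <- sqrt((track$x_um[j] - track$x_um[i])^2 + (track$y_um[j] - track$y_um[i])^2)
    pers <- if (eucl == 0) {
      if (path > 0) message(sprintf("window at t = %g s: zero net displacement, persistence undefined", t[i]))
      NA_real_
    } else if (definition == "paper_literal") path / eucl else eucl / path
    tibble(time_s = t[i], speed_um_min = path / (window_s / 60), persistence = pers)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("motility_record", class(res))
  res
}

#' Event-aligned aspect-ratio and area dynamics
#'
#' Re-zeroes each track's clock at its event time (typically escape
#' completion) and aggregates the shape descriptors across cells per
#' relative time bin — the "elongate while crossing, relax after" readout.
#'
#' @param tracks a `cell_tracks` tibble with shape descriptors (see
#'   [add_shape_descriptors()]).
#' @param event_times a tibble with `track_id` and `t_event_s`.
#' @param bin_s bin width for relative time, s.
#' @return A tibble: `rel_time_s`, `n`, `mean_aspect_ratio`,
#'   `sd_aspect_ratio`, `mean_area_um2`, `sd_area_um2`. Tracks absent from
#'   `event_times` are ignored; no events yields an empty aggregate.
#' @export
align_to_event <- function(tracks, event_times, bin_s = 20) {
  stopifnot(all(c("track_id", "t_event_s") %in% names(event_times)))
  if (!"aspect_ratio" %in% names(tracks)) tracks <- add_shape_descriptors(tracks)
  df <- dplyr::inner_join(tibble::as_tibble(tracks), event_times, by = "track_id")
  if (nrow(df) == 0L) {
    return(tibble(rel_time_s = numeric(0), n = integer(0),
                  mean_aspect_ratio = numeric(0), sd_aspect_ratio = numeric(0),
                  mean_area_um2 = numeric(0), sd_area_um2 = numeric(0)))
  }
  df$rel_time_s <- round((df$time_s - df$t_event_s) / bin_s) * bin_s
  df %>%
    dplyr::group_by(.data$rel_time_s) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean_aspect_ratio = mean(.data$aspect_ratio),
                     sd_aspect_ratio = ifelse(dplyr::n() > 1, sd(.data$aspect_ratio), 0),
                     mean_area_um2 = mean(.data$area_um2),
                     sd_area_um2 = ifelse(dplyr::n() > 1, sd(.data$area_um2), 0),
                     .groups = "drop") %>%
    dplyr::arrange(.data$rel_time_s)
}
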