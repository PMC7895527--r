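# greedy centroid linking and QC filtering of cell tracks

#' Quality-control parameters for track filtering
#'
#' Defaults are the exclusion thresholds used for blebbing-activity
#' quantification: tracks shorter than 200 s are dropped, and a track is
#' excluded outright if at any considered (20 s-resampled) time point the
#' cell area is below 500 px, the centroid moves more than 5 px between
#' consecutive time points, the area changes by more than 10% of the
#' previous area, or the circularity falls below 0.7. Only the first 240 s
#' of each movie are analysed. The pixel thresholds are read at 0.1625
#' µm/px.
#'
#' @param min_area_px minimum cell area per time point, px.
#' @param max_step_disp_px maximum centroid displacement between
#'   consecutive resampled time points, px.
#' @param max_area_change_frac maximum absolute relative area change
#'   between consecutive time points.
#' @param min_circularity minimum circularity (`4*pi*A/P^2`) per time point.
#' @param min_track_duration_s minimum track duration, s.
#' @param analysis_window_s only this initial window is analysed, s.
#' @param resample_interval_s required sampling interval of the tracks, s.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_area_px = 500,
                      max_step_disp_px = 5,
                      max_area_change_frac = 0.10,
                      min_circularity = 0.7,
                      min_track_duration_s = 200,
                      analysis_window_s = 240,
                      resample_interval_s = 20) {
  p <- list(min_area_px = min_area_px,
            max_step_disp_px = max_step_disp_px,
            max_area_change_frac = max_area_change_frac,
            min_circularity = min_circularity,
            min_track_duration_s = min_track_duration_s,
            analysis_window_s = analysis_window_s,
            resample_interval_s = resample_interval_s)
  if (any(unlist(p) <= 0)) stop_bleb("all QC parameters must be positive")
  if (p$analysis_window_s < p$min_track_duration_s) {
    stop_bleb("analysis window must be >= the minimum track duration")
  }
  structure(p, class = "qc_params")
}

region_table <- function(lab, frame_idx, time_s) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0L) {
    return(tibble(frame = integer(0), time_s = numeric(0), label = integer(0),
                  area_px = integer(0), centroid_row = numeric(0),
                  centroid_col = numeric(0), pixels = list()))
  }
  rows <- lapply(ids, function(id) {
    px <- which(lab == id)
    rc <- px_rowcol(px, dim(lab))
    tibble(frame = frame_idx, time_s = time_s, label = id,
           area_px = length(px),
           centroid_row = mean(rc[, "row"]), centroid_col = mean(rc[, "col"]),
           pixels = list(px))
  })
  dplyr::bind_rows(rows)
}

#' Link segmented regions into cell tracks
#'
#' Greedy nearest-centroid frame-to-frame linking: candidate links between
#' the regions of consecutive frames are sorted by centroid distance (ties
#' by smaller label id) and accepted greedily, each region joining at most
#' one track and only when the distance is at most `max_link_dist_px`.
#' Unmatched regions start new tracks; a track with no match simply ends.
#'
#' @param labels a label [movie_stack()].
#' @param max_link_dist_px maximum centroid displacement per frame, px.
#' @return A tibble of class `cell_tracks` with one row per (track, frame):
#'   `track_id`, `time_s`, `frame`, `label`, `area_px`, `centroid_row`,
#'   `centroid_col`, `x_um`, `y_um`, and a `pixels` list-column of linear
#'   pixel indices. Attributes `dim`, `pixel_spacing_um`,
#'   `frame_interval_s` carry the grid metadata.
#' @export
link_tracks <- function(labels, max_link_dist_px = 10) {
  stopifnot(inherits(labels, "movie_stack"))
  if (labels$kind != "label") stop_bleb("`labels` must be a label movie")
  per_frame <- lapply(seq_along(labels$frames), function(k) {
    region_table(labels$frames[[k]], k, labels$timestamps_s[k])
  })
  next_id <- 1L
  out <- list()
  prev <- NULL
  for (k in seq_along(per_frame)) {
    cur <- per_frame[[k]]
    if (nrow(cur)) cur$track_id <- NA_integer_
    if (!is.null(prev) && nrow(prev) && nrow(cur)) {
      cand <- expand.grid(i = seq_len(nrow(prev)), j = seq_len(nrow(cur)))
      cand$dist <- sqrt((prev$centroid_row[cand$i] - cur$centroid_row[cand$j])^2 +
                          (prev$centroid_col[cand$i] - cur$centroid_col[cand$j])^2)
      cand <- cand[cand$dist <= max_link_dist_px, , drop = FALSE]
      cand <- cand[order(cand$dist, cur$label[cand$j]), , drop = FALSE]
      used_i <- logical(nrow(prev)); used_j <- logical(nrow(cur))
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (!used_i[i] && !used_j[j]) {
          used_i[i] <- TRUE; used_j[j] <- TRUE
          cur$track_id[j] <- prev$track_id[i]
        }
      }
    }
    if (nrow(cur) && anyNA(cur$track_id)) {
      nnew <- sum(is.na(cur$track_id))
      cur$track_id[is.na(cur$track_id)] <- next_id + seq_len(nnew) - 1L
      next_id <- next_id + nnew
    }
    out[[k]] <- cur
    prev <- cur
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(track_id = integer(0), frame = integer(0), time_s = numeric(0),
                  label = integer(0), area_px = integer(0),
                  centroid_row = numeric(0), centroid_col = numeric(0),
                  pixels = list())
  }
  s <- labels$pixel_spacing_um
  res$x_um <- (res$centroid_col - 1) * s
  res$y_um <- (res$centroid_row - 1) * s
  res <- dplyr::arrange(res, .data$track_id, .data$frame)
  res <- res[, c("track_id", "time_s", "frame", "label", "area_px",
                 "centroid_row", "centroid_col", "x_um", "y_um", "pixels")]
  new_cell_tracks(res, dim = frame_dim(labels), pixel_spacing_um = s,
                  frame_interval_s = labels$frame_interval_s)
}

new_cell_tracks <- function(df, dim, pixel_spacing_um, frame_interval_s) {
  structure(df,
            dim_px = dim,
            pixel_spacing_um = pixel_spacing_um,
            frame_interval_s = frame_interval_s,
            class = c("cell_tracks", class(tibble::tibble())))
}

# carry cell_tracks attributes through a row subset
subset_tracks <- function(tracks, rows) {
  new_cell_tracks(tracks[rows, , drop = FALSE],
                  dim = attr(tracks, "dim_px"),
                  pixel_spacing_um = attr(tracks, "pixel_spacing_um"),
                  frame_interval_s = attr(tracks, "frame_interval_s"))
}

#' Apply the track-level quality-control exclusion filters
#'
#' A track is removed iff its duration is below
#' `qc$min_track_duration_s` OR any considered time point violates the
#' area, displacement, area-change or circularity thresholds (see
#' [qc_params()]). Tracks must already be resampled to
#' `qc$resample_interval_s`; time points beyond `qc$analysis_window_s` are
#' not considered. Displacement is centroid displacement between
#' consecutive resampled time points; area change is the absolute relative
#' change versus the previous time point.
#'
#' @param tracks a `cell_tracks` tibble (from [link_tracks()]), resampled.
#' @param qc a [qc_params()] object.
#' @return A list with `kept` (the surviving `cell_tracks`) and `report`, a
#'   tibble with per-reason exclusion counts (`reason`, `n_tracks`; a track
#'   failing several rules is counted under each) plus `kept` / `total`
#'   attributes columns `n_total`, `n_kept`.
#' @export
filter_tracks <- function(tracks, qc = qc_params()) {
  stopifnot(inherits(tracks, "cell_tracks"))
  dt <- attr(tracks, "frame_interval_s")
  if (is.null(dt) || abs(dt - qc$resample_interval_s) > 1e-9) {
    stop_bleb("tracks are sampled at %s s but QC expects %g s; resample first",
              format(dt), qc$resample_interval_s)
  }
  spacing <- attr(tracks, "pixel_spacing_um")
  dim <- attr(tracks, "dim_px")
  tracks_w <- tracks[tracks$time_s <= qc$analysis_window_s + 1e-9, , drop = FALSE]
  ids <- unique(tracks_w$track_id)
  verdict <- lapply(ids, function(id) {
    tr <- tracks_w[tracks_w$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$time_s), , drop = FALSE]
    reasons <- character(0)
    if (diff(range(tr$time_s)) < qc$min_track_duration_s) reasons <- c(reasons, "duration")
    if (any(tr$area_px < qc$min_area_px)) reasons <- c(reasons, "area")
    if (nrow(tr) > 1) {
      disp <- sqrt(diff(tr$centroid_row)^2 + diff(tr$centroid_col)^2)
      if (any(disp > qc$max_step_disp_px)) reasons <- c(reasons, "displacement")
      dA <- abs(diff(tr$area_px)) / head(tr$area_px, -1)
      if (any(dA > qc$max_area_change_frac)) reasons <- c(reasons, "area_change")
    }
    circ <- vapply(tr$pixels, function(px) {
      shape_descriptors(mask_from_px(px, dim), spacing)$circularity
    }, numeric(1))
    if (any(circ < qc$min_circularity)) reasons <- c(reasons, "circularity")
    reasons
  })
  names(verdict) <- as.character(ids)
  excluded <- ids[lengths(verdict) > 0]
  all_reasons <- c("duration", "area", "displacement", "area_change", "circularity")
  report <- tibble(
    reason = all_reasons,
    n_tracks = vapply(all_reasons, function(r) {
      sum(vapply(verdict, function(v) r %in% v, logical(1)))
    }, numeric(1)),
    n_total = length(ids),
    n_kept = length(ids) - length(excluded))
  kept <- subset_tracks(tracks_w, !(tracks_w$track_id %in% excluded))
  list(kept = kept, report = report)
}

#' Resample tracks by resampling their source movie
#'
#' Convenience wrapper: tracks carry masks per frame, so temporal
#' resampling keeps the rows nearest each target time. Equivalent to
#' resampling the movie first and re-linking.
#'
#' @param tracks a `cell_tracks` tibble.
#' @param target_interval_s target interval, s.
#' @param duration_s optional truncation, s.
#' @return A `cell_tracks` tibble on the target time grid.
#' @export
resample_tracks <- function(tracks, target_interval_s = 20, duration_s = NULL) {
  stopifnot(inherits(tracks, "cell_tracks"))
  dt <- attr(tracks, "frame_interval_s")
  if (dt > target_interval_s) {
    stop_bleb("track interval (%g s) exceeds the target (%g s)", dt, target_interval_s)
  }
  ts <- sort(unique(tracks$time_s))
  tmax <- max(ts)
  if (!is.null(duration_s)) tmax <- min(tmax, duration_s)
  targets <- seq(0, tmax, by = target_interval_s)
  pick <- ts[vapply(targets, function(t) which.min(abs(ts - t)), integer(1))]
  out <- tracks[tracks$time_s %in% pick, , drop = FALSE]
  out$time_s <- targets[match(out$time_s, pick)]
  res <- new_cell_tracks(out, dim = attr(tracks, "dim_px"),
                         pixel_spacing_um = attr(tracks, "pixel_spacing_um"),
                         frame_interval_s = target_interval_s)
  res
}

#' Build tracks directly from a ground-truth label movie
#'
#' When labels are already consistent across frames (simulator output),
#' tracking reduces to reading the per-frame regions of each id.
#'
#' @param labels a label [movie_stack()] with frame-consistent ids.
#' @return A `cell_tracks` tibble with `track_id` equal to the label id.
#' @export
tracks_from_labels <- function(labels) {
  stopifnot(inherits(labels, "movie_stack"), labels$kind == "label")
  per_frame <- lapply(seq_along(labels$frames), function(k) {
    region_table(labels$frames[[k]], k, labels$timestamps_s[k])
  })
  res <- dplyr::bind_rows(per_frame)
  res$track_id <- res$label
  s <- labels$pixel_spacing_um
  res$x_um <- (res$centroid_col - 1) * s
  res$y_um <- (res$centroid_row - 1) * s
  res <- dplyr::arrange(res, .data$track_id, .data$frame)
  res <- res[, c("track_id", "time_s", "frame", "label", "area_px",
                 "centroid_row", "centroid_col", "x_um", "y_um", "pixels")]
  new_cell_tracks(res, dim = frame_dim(labels), pixel_spacing_um = s,
                  frame_interval_s = labels$frame_interval_s)
}
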