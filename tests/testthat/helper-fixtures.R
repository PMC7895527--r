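# fixtures and independent brute-force oracles used across the suite

disc_mask <- function(n, center, r) {
  g <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix(FALSE, n, n)
  m[as.matrix(g[(g$row - center[1])^2 + (g$col - center[2])^2 <= r^2, ])] <- TRUE
  m
}

ellipse_mask <- function(n, center, a_col, b_row, theta = 0) {
  g <- expand.grid(row = 1:n, col = 1:n)
  dx <- g$col - center[2]
  dy <- g$row - center[1]
  u <- (dx * cos(theta) + dy * sin(theta)) / a_col
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_row
  m <- matrix(FALSE, n, n)
  m[as.matrix(g[u^2 + v^2 <= 1, ])] <- TRUE
  m
}

# brute-force pixel-set symmetric difference via logical matrix algebra
oracle_diff <- function(m_now, m_prev) {
  list(gained = which(m_now & !m_prev),
       lost = which(!m_now & m_prev),
       gained_area = sum(m_now & !m_prev),
       lost_area = sum(!m_now & m_prev))
}

# brute-force blebbing activity: explicit per-step masks and mean by summation
oracle_activity <- function(masks, areas) {
  vals <- numeric(length(masks) - 1)
  for (k in seq_along(vals)) {
    d <- oracle_diff(masks[[k + 1]], masks[[k]])
    vals[k] <- (d$gained_area + d$lost_area) / areas[k + 1]
  }
  sum(vals) / length(vals)
}

# brute-force per-pixel boundary distances (explicit loop)
oracle_boundary <- function(mask, center, radius, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  d <- numeric(nrow(idx))
  outside <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    x <- (idx[i, "col"] - 1) * spacing
    y <- (idx[i, "row"] - 1) * spacing
    rr <- sqrt((x - center[1])^2 + (y - center[2])^2)
    d[i] <- abs(rr - radius)
    outside[i] <- rr > radius
  }
  list(front = min(d), rear = max(d), frac_outside = mean(outside))
}

# brute-force exact Mann-Whitney two-sided p by labeling enumeration on the
# raw values (independent of the implementation's rank-based route)
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  dev <- abs(u_obs - nx * length(y) / 2)
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(u_all - nx * length(y) / 2) >= dev - 1e-12)
}

# small helper: single-track subset keeping cell_tracks attributes
one_track <- function(tracks, id) {
  blebquant:::subset_tracks(tracks, tracks$track_id == id)
}

# hand-built cell_tracks table from a list of masks at given times
tracks_from_masks <- function(masks, times, spacing = 0.1625, interval = 20,
                              track_id = 1L) {
  stopifnot(length(masks) == length(times))
  dim <- dim(masks[[1]])
  rows <- lapply(seq_along(masks), function(k) {
    px <- which(masks[[k]])
    rc <- blebquant:::px_rowcol(px, dim)
    tibble::tibble(track_id = track_id, time_s = times[k], frame = k,
                   label = track_id, area_px = length(px),
                   centroid_row = mean(rc[, "row"]),
                   centroid_col = mean(rc[, "col"]),
                   x_um = (mean(rc[, "col"]) - 1) * spacing,
                   y_um = (mean(rc[, "row"]) - 1) * spacing,
                   pixels = list(px))
  })
  blebquant:::new_cell_tracks(dplyr::bind_rows(rows), dim = dim,
                              pixel_spacing_um = spacing,
                              frame_interval_s = interval)
}

bind_tracks <- function(...) {
  trs <- list(...)
  blebquant:::new_cell_tracks(dplyr::bind_rows(lapply(trs, tibble::as_tibble)),
                              dim = attr(trs[[1]], "dim_px"),
                              pixel_spacing_um = attr(trs[[1]], "pixel_spacing_um"),
                              frame_interval_s = attr(trs[[1]], "frame_interval_s"))
}
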