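# classical intensity-based segmentation, drift registration, resampling

#' Segment one intensity frame into cell labels
#'
#' A classical pipeline standing in for learned segmenters: Gaussian
#' smoothing, background subtraction (image minimum after smoothing),
#' automatic global threshold (Otsu on the intensity histogram), hole
#' filling, then splitting of touching objects by a watershed on the
#' distance transform (distance-transform maxima act as seeds). Objects
#' smaller than `min_object_px` are discarded. Objects are 8-connected.
#'
#' @param image a single-channel numeric matrix.
#' @param min_object_px minimum object size in pixels.
#' @param smoothing_um Gaussian smoothing sigma in µm (kept small so the
#'   bright cortex rim does not displace the threshold crossing outward).
#' @param spacing_um pixel spacing, µm/px.
#' @param watershed_tolerance minimum depth between distance-map maxima for
#'   objects to be split (px).
#' @return An integer label matrix (0 = background). A blank or constant
#'   frame yields an all-zero matrix.
#' @export
segment_frame <- function(image, min_object_px = 100L, smoothing_um = 0.1,
                          spacing_um = 0.1625, watershed_tolerance = 1) {
  stopifnot(is.matrix(image), is.numeric(image))
  rng <- range(image)
  if (!all(is.finite(rng)) || diff(rng) == 0) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(image),
                                 sigma = max(smoothing_um / spacing_um, 0.5)))
  sm <- sm - min(sm)
  norm <- sm / max(sm)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (any(bw) && !all(bw)) {
    # second pass: centre the edge between the background and foreground
    # levels (Otsu can sit high when a bright cortex class is present)
    thr2 <- (stats::median(norm[!bw]) + stats::median(norm[bw])) / 2
    bw <- norm > thr2
  }
  bw <- as.matrix(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  if (!any(bw)) return(matrix(0L, nrow(image), ncol(image)))
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  lab <- as.matrix(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))
  # drop small objects and relabel compactly
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_object_px)
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Segment every frame of an intensity movie
#'
#' @param movie an intensity [movie_stack()].
#' @inheritParams segment_frame
#' @return A label [movie_stack()] with the same timestamps.
#' @export
segment_movie <- function(movie, min_object_px = 100L, smoothing_um = 0.1,
                          watershed_tolerance = 1) {
  stopifnot(inherits(movie, "movie_stack"))
  frames <- lapply(movie$frames, segment_frame,
                   min_object_px = min_object_px, smoothing_um = smoothing_um,
                   spacing_um = movie$pixel_spacing_um,
                   watershed_tolerance = watershed_tolerance)
  movie_stack(frames, movie$pixel_spacing_um, movie$frame_interval_s,
              kind = "label", timestamps_s = movie$timestamps_s)
}

# integer-pixel translation with constant (0) padding
shift_frame <- function(f, dr, dc) {
  out <- matrix(if (is.integer(f)) 0L else 0, nrow(f), ncol(f))
  nr <- nrow(f); nc <- ncol(f)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(src_r) == 0 || length(src_c) == 0) return(out)
  out[src_r + dr, src_c + dc] <- f[src_r, src_c]
  out
}

# FFT cross-correlation peak between two equally sized matrices; returns the
# integer (dr, dc) such that shifting `b` by -(dr, dc) aligns it onto `a`
xcorr_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) return(c(0L, 0L, flat = 1L))
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  peak <- which.max(cc)
  nr <- nrow(a)
  dr <- ((peak - 1) %% nr)
  dc <- ((peak - 1) %/% nr)
  if (dr > nr / 2) dr <- dr - nr
  if (dc > ncol(a) / 2) dc <- dc - ncol(a)
  c(as.integer(dr), as.integer(dc), flat = 0L)
}

#' Register a movie to its first frame
#'
#' Translation-only registration compensating global stage drift: each frame
#' is aligned to frame 1 by the integer-pixel shift maximising the FFT
#' cross-correlation, then translated with constant (zero) padding at the
#' edges. A degenerate (flat) correlation yields a zero shift and a message.
#'
#' @param movie a [movie_stack()] (label or intensity).
#' @return A list with `movie` (registered) and `shifts`, a tibble with one
#'   row per frame: `frame`, `shift_row`, `shift_col` (pixels; the shift
#'   *applied* to bring the frame onto frame 1).
#' @export
register_movie <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  ref <- movie$frames[[1]]
  n <- length(movie$frames)
  shifts <- matrix(0L, n, 2)
  frames <- movie$frames
  for (k in seq_len(n)[-1]) {
    sh <- xcorr_shift(ref, movie$frames[[k]])
    if (sh[["flat"]] == 1L) {
      message(sprintf("frame %d: flat cross-correlation, assuming zero shift", k))
    }
    shifts[k, ] <- sh[1:2]
    if (any(sh[1:2] != 0L)) {
      frames[[k]] <- shift_frame(movie$frames[[k]], sh[1], sh[2])
    }
  }
  out <- movie_stack(frames, movie$pixel_spacing_um, movie$frame_interval_s,
                     kind = movie$kind, timestamps_s = movie$timestamps_s)
  list(movie = out,
       shifts = tibble(frame = seq_len(n),
                       shift_row = shifts[, 1], shift_col = shifts[, 2]))
}

#' Resample a movie to a coarser frame interval
#'
#' Keeps the frame nearest each target timestamp `0, dt, 2 dt, ...` (ties go
#' to the earlier frame); masks are never interpolated. Optionally truncates
#' to the first `duration_s` seconds. Standard use: resample to 1 frame per
#' 20 s and keep the first 240 s before computing blebbing activity.
#'
#' @param movie a [movie_stack()].
#' @param target_interval_s target interval, s; must be >= the movie's
#'   native interval.
#' @param duration_s optional truncation: keep target times `<= duration_s`.
#' @return A [movie_stack()] on the target time grid.
#' @export
resample_movie <- function(movie, target_interval_s = 20, duration_s = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (movie$frame_interval_s > target_interval_s) {
    stop_bleb("movie interval (%g s) exceeds the target (%g s); masks cannot be interpolated",
              movie$frame_interval_s, target_interval_s)
  }
  tmax <- max(movie$timestamps_s)
  if (!is.null(duration_s)) tmax <- min(tmax, duration_s)
  targets <- seq(0, tmax, by = target_interval_s)
  idx <- vapply(targets, function(t) {
    which.min(abs(movie$timestamps_s - t)) # which.min takes the first tie
  }, integer(1))
  movie_stack(movie$frames[idx], movie$pixel_spacing_um,
              frame_interval_s = target_interval_s,
              kind = movie$kind, timestamps_s = targets)
}
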