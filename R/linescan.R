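# fluorescence linescans, peak detection, cortical/cytoplasmic ratio

#' Intensity linescan along a segment
#'
#' Samples the image along the segment from `p0_um` to `p1_um` at <= 1 px
#' spacing with bilinear interpolation, averaging over `width_px`
#' perpendicular offsets (1 px apart, centred on the line). The classic
#' readout: a line through a cell with a labelled cortex shows two peaks
#' where it crosses the cortex.
#'
#' @param image numeric matrix.
#' @param p0_um,p1_um segment endpoints `(x, y)` in µm.
#' @param width_px number of perpendicular 1-px-spaced lines to average.
#' @param spacing_um pixel spacing, µm/px.
#' @return A tibble of class `linescan_profile`: `position_um` (distance
#'   from `p0_um`), `intensity` (AU). Attributes carry the endpoints and
#'   averaging width.
#' @export
linescan <- function(image, p0_um, p1_um, width_px = 1L, spacing_um = 0.1625) {
  stopifnot(is.matrix(image), length(p0_um) == 2L, length(p1_um) == 2L)
  to_rc <- function(p) c(row = p[2] / spacing_um + 1, col = p[1] / spacing_um + 1)
  rc0 <- to_rc(p0_um); rc1 <- to_rc(p1_um)
  for (rc in list(rc0, rc1)) {
    if (rc["row"] < 1 || rc["row"] > nrow(image) ||
        rc["col"] < 1 || rc["col"] > ncol(image)) {
      stop_bleb("linescan endpoint (%.2f, %.2f) um lies outside the image", p0_um[1], p0_um[2])
    }
  }
  len_px <- sqrt(sum((rc1 - rc0)^2))
  n <- max(ceiling(len_px), 1L) + 1L
  f <- seq(0, 1, length.out = n)
  rows <- rc0["row"] + f * (rc1["row"] - rc0["row"])
  cols <- rc0["col"] + f * (rc1["col"] - rc0["col"])
  # unit normal in (row, col) space
  dvec <- c(rc1["row"] - rc0["row"], rc1["col"] - rc0["col"])
  dlen <- sqrt(sum(dvec^2))
  nvec <- if (dlen > 0) c(-dvec[2], dvec[1]) / dlen else c(0, 0)
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  prof <- rowMeans(vapply(offsets, function(o) {
    r <- pmin(pmax(rows + o * nvec[1], 1), nrow(image))
    cc <- pmin(pmax(cols + o * nvec[2], 1), ncol(image))
    interp_bilinear(image, r, cc)
  }, numeric(n)))
  res <- tibble(position_um = f * len_px * spacing_um, intensity = prof)
  attr(res, "p0_um") <- p0_um
  attr(res, "p1_um") <- p1_um
  attr(res, "averaging_width_px") <- width_px
  class(res) <- c("linescan_profile", class(res))
  res
}

#' Detect peaks in a linescan profile by prominence
#'
#' Local maxima (plateaus count once, at their centre) whose topographic
#' prominence is at least `min_prominence_frac` of the profile's full
#' range. A flat profile has no peaks.
#'
#' @param profile a `linescan_profile` (or tibble with `position_um`,
#'   `intensity`).
#' @param min_prominence_frac prominence threshold as a fraction of
#'   `max - min` of the profile.
#' @return A tibble: `position_um`, `intensity`, `prominence` of each peak,
#'   ordered by position.
#' @export
detect_peaks <- function(profile, min_prominence_frac = 0.2) {
  stopifnot(all(c("position_um", "intensity") %in% names(profile)))
  y <- profile$intensity
  n <- length(y)
  empty <- tibble(position_um = numeric(0), intensity = numeric(0),
                  prominence = numeric(0))
  if (n < 3L) return(empty)
  rng <- diff(range(y))
  if (rng == 0) return(empty)
  # local maxima with plateau handling
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) {
        peaks <- c(peaks, as.integer(round((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(peaks) == 0L) return(empty)
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    # valley floor between this peak and the nearest higher ground, per side
    left <- y[seq_len(p - 1L)]
    lh <- which(left > h)
    left_base <- if (length(lh) == 0L) min(left) else min(left[(max(lh) + 1L):(p - 1L)])
    right <- y[(p + 1L):n]
    rh <- which(right > h)
    right_base <- if (length(rh) == 0L) min(right) else min(right[seq_len(min(rh) - 1L)])
    h - max(left_base, right_base)
  }, numeric(1))
  keep <- prom >= min_prominence_frac * rng
  tibble(position_um = profile$position_um[peaks[keep]],
         intensity = y[peaks[keep]],
         prominence = prom[keep])
}

#' Cortical / cytoplasmic fluorescence ratio
#'
#' Quantifies cortical enrichment of a marker (e.g. F-actin or myosin
#' regulatory light chain): the cortex region is the band of mask pixels
#' within `cortex_band_um` of the mask boundary, the cytoplasm the
#' remaining interior, and the ratio the quotient of their mean
#' intensities. An unspecified-procedure approximation: region means over
#' a fixed-width boundary band (default 0.5 µm, matching the visible
#' cortex width); a peak-height alternative is available by combining
#' [linescan()] with [detect_peaks()]. Optionally a constant background is
#' subtracted from both means first.
#'
#' @param image numeric intensity matrix.
#' @param mask logical cell mask.
#' @param cortex_band_um band width, µm; must leave a non-empty interior.
#' @param spacing_um pixel spacing, µm/px.
#' @param background constant background intensity subtracted before the
#'   ratio (default 0).
#' @return A list of class `cortex_ratio`: `ratio`, `cortex_band_um`,
#'   `cortex_mean_AU`, `cytoplasm_mean_AU`, `n_cortex_px`, `n_cytoplasm_px`.
#' @export
cortical_cytoplasmic_ratio <- function(image, mask, cortex_band_um = 0.5,
                                       spacing_um = 0.1625, background = 0) {
  stopifnot(is.matrix(image), is.matrix(mask),
            identical(dim(image), dim(mask)))
  mask <- mask != 0
  if (!any(mask)) stop_bleb("empty mask")
  band_px <- cortex_band_um / spacing_um
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  cortex <- mask & dm <= band_px
  cyto <- mask & dm > band_px
  if (!any(cyto)) {
    stop_bleb("cortex band (%.2f um) swallows the whole cell; reduce cortex_band_um",
              cortex_band_um)
  }
  cm <- mean(image[cortex]) - background
  ym <- mean(image[cyto]) - background
  structure(list(ratio = cm / ym,
                 cortex_band_um = cortex_band_um,
                 cortex_mean_AU = cm,
                 cytoplasm_mean_AU = ym,
                 n_cortex_px = sum(cortex),
                 n_cytoplasm_px = sum(cyto)),
            class = "cortex_ratio")
}

#' @export
print.cortex_ratio <- function(x, ...) {
  cat(sprintf("<cortex_ratio> %.3f (cortex %.1f AU / cytoplasm %.1f AU, band %.2f um)\n",
              x$ratio, x$cortex_mean_AU, x$cytoplasm_mean_AU, x$cortex_band_um))
  invisible(x)
}
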