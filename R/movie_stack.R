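#' Movie stack container
#'
#' An ordered set of equally shaped 2-D frames plus the physical metadata
#' every downstream computation needs: the pixel spacing (µm/px) and the
#' frame timestamps (s). Frames are either integer label images (background
#' `0`, one positive integer id per cell) or real-valued intensity images.
#'
#' @param frames list of matrices, all with identical dimensions.
#' @param pixel_spacing_um pixel spacing in micrometres per pixel.
#' @param frame_interval_s nominal interval between frames in seconds.
#' @param kind `"label"` or `"intensity"`.
#' @param timestamps_s optional numeric vector of frame times (s); defaults
#'   to `0, frame_interval_s, 2 * frame_interval_s, ...`.
#'
#' @return An object of class `movie_stack`: a list with elements `frames`,
#'   `kind`, `pixel_spacing_um`, `frame_interval_s`, `timestamps_s`.
#' @export
#' @examples
#' f <- matrix(0L, 32, 32); f[10:20, 10:20] <- 1L
#' mv <- movie_stack(list(f, f), pixel_spacing_um = 0.1625, frame_interval_s = 5)
#' mv
movie_stack <- function(frames, pixel_spacing_um, frame_interval_s,
                        kind = c("label", "intensity"), timestamps_s = NULL) {
  kind <- match.arg(kind)
  if (!is.list(frames) || length(frames) == 0L) {
    stop_bleb("`frames` must be a non-empty list of matrices")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_bleb("all frames must share the same dimensions")
  }
  assert_scalar_num(pixel_spacing_um, "pixel_spacing_um", 0, strict = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  if (is.null(timestamps_s)) {
    timestamps_s <- (seq_along(frames) - 1) * frame_interval_s
  }
  if (length(timestamps_s) != length(frames) ||
      any(diff(timestamps_s) <= 0)) {
    stop_bleb("`timestamps_s` must match frame count and be strictly increasing")
  }
  structure(
    list(frames = frames, kind = kind,
         pixel_spacing_um = pixel_spacing_um,
         frame_interval_s = frame_interval_s,
         timestamps_s = as.numeric(timestamps_s)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<movie_stack> %d frames of %d x %d px (%s), %.4g um/px, t = %g..%g s\n",
    length(x$frames), d[1], d[2], x$kind, x$pixel_spacing_um,
    min(x$timestamps_s), max(x$timestamps_s)))
  invisible(x)
}

#' @export
length.movie_stack <- function(x) length(x$frames)

frame_dim <- function(movie) dim(movie$frames[[1]])

#' Write / read a movie as multi-page TIFF with a JSON metadata sidecar
#'
#' Movies are stored as 16-bit multi-page TIFF (one page per frame) with a
#' `<file>.json` sidecar carrying the pixel spacing, frame interval,
#' timestamps and kind. Label movies store the integer ids directly;
#' intensity movies are stored as rounded 16-bit counts.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   returns a [movie_stack()].
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  scaled <- lapply(movie$frames, function(f) {
    m <- pmin(pmax(round(f), 0), 65535)
    m / 65535 # tiff::writeTIFF takes [0,1] and scales by bit depth
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  meta <- list(kind = movie$kind,
               pixel_spacing_um = movie$pixel_spacing_um,
               frame_interval_s = movie$frame_interval_s,
               timestamps_s = movie$timestamps_s)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(pages, function(p) {
    m <- round(p * 65535)
    if (identical(meta$kind, "label")) storage.mode(m) <- "integer"
    m
  })
  movie_stack(frames,
              pixel_spacing_um = meta$pixel_spacing_um,
              frame_interval_s = meta$frame_interval_s,
              kind = meta$kind,
              timestamps_s = meta$timestamps_s)
}

#' Write / read simulator ground truth as JSON
#'
#' The simulator's event log: true tracks, bleb nucleation events, phenotype
#' labels, the programmed escape record and the rendered cortex/cytoplasm
#' ratio (when applicable). The JSON schema mirrors the list structure:
#' data frames become arrays of row objects.
#'
#' @param gt a `ground_truth` object from the simulators.
#' @param path JSON path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` the `ground_truth` list.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("true_tracks", "bleb_events", "phenotypes", "escape")) {
    if (!is.null(x[[nm]]) && is.data.frame(x[[nm]])) {
      x[[nm]] <- tibble::as_tibble(x[[nm]])
    }
  }
  structure(x, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells, %d bleb events%s\n",
              nrow(x$phenotypes), nrow(x$bleb_events),
              if (!is.null(x$escape)) ", escape record" else ""))
  invisible(x)
}
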