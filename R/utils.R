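# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bleb <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "blebquant_error")

assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bleb("`%s` must be a finite numeric scalar", name)
  }
  if (strict && x <= min) stop_bleb("`%s` must be > %g", name, min)
  if (!strict && x < min) stop_bleb("`%s` must be >= %g", name, min)
  invisible(x)
}

# pixel sets: masks are stored as sorted integer vectors of linear indices
# into an nrow x ncol frame; cheap set algebra replaces full logical matrices
px_from_mask <- function(mask) which(mask != 0)

mask_from_px <- function(px, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[px] <- TRUE
  m
}

px_rowcol <- function(px, dim) {
  cbind(row = ((px - 1L) %% dim[1]) + 1L, col = ((px - 1L) %/% dim[1]) + 1L)
}

# centroid of a pixel set in physical units; pixel centers at (i-1)*spacing
px_centroid_um <- function(px, dim, spacing_um) {
  rc <- px_rowcol(px, dim)
  c(x = (mean(rc[, "col"]) - 1) * spacing_um,
    y = (mean(rc[, "row"]) - 1) * spacing_um)
}

# 8-connected components of a pixel set (EBImage::bwlabel is 4-connected);
# returns a list of integer index vectors
label_components8 <- function(px, dim) {
  if (length(px) == 0L) return(list())
  nr <- dim[1]
  inset <- new.env(hash = TRUE, size = length(px))
  for (p in px) assign(as.character(p), TRUE, envir = inset)
  seen <- new.env(hash = TRUE, size = length(px))
  rc <- px_rowcol(px, dim)
  offsets <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  comps <- list()
  for (k in seq_along(px)) {
    p0 <- px[k]
    if (!is.null(seen[[as.character(p0)]])) next
    queue <- p0
    assign(as.character(p0), TRUE, envir = seen)
    comp <- integer(0)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, p)
      r <- ((p - 1L) %% nr) + 1L
      for (off in offsets) {
        q <- p + off
        # guard against row wrap-around at matrix edges
        qr <- ((q - 1L) %% nr) + 1L
        if (abs(qr - r) > 1L) next
        if (q < 1L || q > dim[1] * dim[2]) next
        key <- as.character(q)
        if (!is.null(inset[[key]]) && is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          queue <- c(queue, q)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# bilinear interpolation of matrix values at fractional (row, col) positions
interp_bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(floor(row), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(col), 1L), nc - 1L)
  fr <- row - r0
  fc <- col - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1L, c0)]
  v01 <- img[cbind(r0, c0 + 1L)]
  v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# deterministic per-cell substream seed derived from the master seed, so that
# cell i's trajectory is unchanged when n_cells changes
cell_subseed <- function(seed, cell_id) {
  (as.integer(seed) %% 100000L) * 10007L + 7919L * as.integer(cell_id)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
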