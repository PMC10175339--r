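# Internal helpers shared across modules.

#' @noRd
assert_image <- function(img, name = "image", min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("`%s` is too small (%dx%d); need at least %dx%d",
                 name, nrow(img), ncol(img), min_dim, min_dim), call. = FALSE)
  }
  invisible(img)
}

# Error out naming the first non-finite pixel (0-based x = column, y = row).
#' @noRd
assert_finite_image <- function(img, name = "image") {
  bad <- which(!is.finite(img))
  if (length(bad) > 0L) {
    i <- bad[[1L]]
    y <- (i - 1L) %% nrow(img)
    x <- (i - 1L) %/% nrow(img)
    stop(sprintf("`%s` contains a non-finite value at (x=%d, y=%d)", name, x, y),
         call. = FALSE)
  }
  invisible(img)
}

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Min-max normalization to [0, 1]; constant input maps to all zeros.
#' @noRd
minmax_norm <- function(img) {
  r <- range(img)
  if (r[2] - r[1] <= 0) return(img * 0)
  (img - r[1]) / (r[2] - r[1])
}

# Mirror (symmetric) padding of a matrix.
#' @noRd
pad_mirror <- function(img, top, bottom, left, right) {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(idx, n) {
    # reflect indices into 1..n (symmetric, edge pixel not repeated when possible)
    idx <- abs(idx - 1L) %% (2L * n - 2L)
    idx <- ifelse(idx >= n, 2L * n - 2L - idx, idx)
    idx + 1L
  }
  if (nr == 1L) rid <- rep(1L, top + nr + bottom) else rid <- refl(seq.int(1L - top, nr + bottom), nr)
  if (nc == 1L) cid <- rep(1L, left + nc + right) else cid <- refl(seq.int(1L - left, nc + right), nc)
  img[rid, cid, drop = FALSE]
}

# 2-D FFT / inverse FFT on matrices.
#' @noRd
fft2 <- function(x) stats::fft(x)
#' @noRd
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Summed-area table with a leading zero row/col, so box sums are O(1).
#' @noRd
integral_image <- function(img) {
  s <- apply(img, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# Sum of img over rows (r0+1)..r1 and cols (c0+1)..c1 (1-based, inclusive upper).
#' @noRd
sat_boxsum <- function(sat, r0, r1, c0, c1) {
  sat[cbind(r1 + 1L, c1 + 1L)] - sat[cbind(r0 + 1L, c1 + 1L)] -
    sat[cbind(r1 + 1L, c0 + 1L)] + sat[cbind(r0 + 1L, c0 + 1L)]
}

# Bilinear sampling of `img` at continuous 0-based pixel coords (x = col, y = row).
# Out-of-bounds samples take `fill` (default: image mean).
#' @noRd
bilinear_sample <- function(img, x, y, fill = mean(img)) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp the upper neighbour so edge pixels interpolate with themselves
  x1 <- pmax(pmin(x0 + 1, nc - 1), 0); y1 <- pmax(pmin(y0 + 1, nr - 1), 0)
  x0c <- pmax(pmin(x0, nc - 1), 0); y0c <- pmax(pmin(y0, nr - 1), 0)
  idx <- function(yy, xx) yy + 1L + xx * nr
  v <- (1 - fy) * ((1 - fx) * img[idx(y0c, x0c)] + fx * img[idx(y0c, x1)]) +
    fy * ((1 - fx) * img[idx(y1, x0c)] + fx * img[idx(y1, x1)])
  v[!inside] <- fill
  v
}

# Resample `img` into an output grid, where `map_out_to_in` sends 0-based
# output pixel coords to 0-based input coords.
#' @noRd
warp_image <- function(img, map_out_to_in, out_shape, fill = mean(img)) {
  nr <- out_shape[1]; nc <- out_shape[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  p <- apply_affine(map_out_to_in, cbind(xs, ys))
  matrix(bilinear_sample(img, p[, 1], p[, 2], fill = fill), nrow = nr, ncol = nc)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
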