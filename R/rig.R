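# Calibration-rig (checkerboard) corner detection and the scale-adjustment map.

# Checker corner response at every pixel for quadrant half-width w, via a
# summed-area table: |TL + BR - TR - BL| / (4 w^2). Polarity-agnostic, so the
# inverted contrast of the rig in the thermal modality does not matter.
#' @noRd
checker_response <- function(sat, nr, nc, w) {
  out <- matrix(0, nr, nc)
  rows <- (w + 1L):(nr - w)
  cols <- (w + 1L):(nc - w)
  if (length(rows) < 1L || length(cols) < 1L) return(out)
  R <- rep(rows, times = length(cols))
  C <- rep(cols, each = length(rows))
  tl <- sat_boxsum(sat, R - w - 1L, R - 1L, C - w - 1L, C - 1L)
  br <- sat_boxsum(sat, R, R + w - 1L, C, C + w - 1L)
  tr <- sat_boxsum(sat, R - w - 1L, R - 1L, C, C + w - 1L)
  bl <- sat_boxsum(sat, R, R + w - 1L, C - w - 1L, C - 1L)
  out[cbind(R, C)] <- abs(tl + br - tr - bl) / (4 * w * w)
  out
}

# Subpixel refinement: quadratic interpolation of the response peak.
#' @noRd
subpixel_peak <- function(resp, r, c) {
  nr <- nrow(resp); nc <- ncol(resp)
  dx <- 0; dy <- 0
  if (c > 1L && c < nc) {
    den <- resp[r, c - 1L] - 2 * resp[r, c] + resp[r, c + 1L]
    if (den < 0) dx <- 0.5 * (resp[r, c - 1L] - resp[r, c + 1L]) / den
  }
  if (r > 1L && r < nr) {
    den <- resp[r - 1L, c] - 2 * resp[r, c] + resp[r + 1L, c]
    if (den < 0) dy <- 0.5 * (resp[r - 1L, c] - resp[r + 1L, c]) / den
  }
  c(x = c - 1 + max(min(dx, 0.5), -0.5), y = r - 1 + max(min(dy, 0.5), -0.5))
}

#' Find checkerboard inner corners
#'
#' Detects the inner-corner lattice of a near-axis-aligned checkerboard by a
#' multi-scale quadrant-contrast response (polarity-agnostic, so it works on
#' both the visible board and its inverted-contrast thermal rendering), orders
#' the corners row-major (top-to-bottom, left-to-right), and refines each to
#' subpixel accuracy.
#'
#' @param img Numeric matrix.
#' @param dims Inner-corner grid `c(rows, cols)`.
#' @param min_response Minimum normalised quadrant contrast for a corner to
#'   count (on the min-max-normalised image); guards against boards that are
#'   not actually present.
#' @return n x 2 matrix of 0-based `(x, y)` corner coordinates, row-major, or
#'   an error of class `rgbtresp_rig_error` when no plausible board is found.
#' @export
find_checkerboard_corners <- function(img, dims, min_response = 0.15) {
  assert_image(img, min_dim = 16L)
  rows <- as.integer(dims[1]); cols <- as.integer(dims[2])
  n_corners <- rows * cols
  g <- minmax_norm(img)
  sat <- integral_image(g)
  nr <- nrow(g); nc <- ncol(g)
  best <- NULL
  for (w in c(2L, 3L, 4L, 6L, 8L, 12L, 16L)) {
    if (2L * w + 1L > min(nr, nc)) break
    resp <- checker_response(sat, nr, nc, w)
    pk <- local_peaks(resp, radius = max(w, 3L), n = n_corners)
    if (nrow(pk) < n_corners) next
    strength <- min(pk$value)
    if (is.null(best) || strength > best$strength) {
      best <- list(w = w, resp = resp, pk = pk, strength = strength)
    }
  }
  if (is.null(best) || best$strength < min_response) {
    cond <- structure(class = c("rgbtresp_rig_error", "error", "condition"),
                      list(message = sprintf(
                        "checkerboard with %dx%d inner corners not found", rows, cols),
                        call = NULL))
    stop(cond)
  }
  pts <- t(vapply(seq_len(n_corners),
                  function(i) subpixel_peak(best$resp, best$pk$r[i], best$pk$c[i]),
                  c(x = 0, y = 0)))
  # order row-major: cluster into `rows` bands by y, sort by x within each
  o <- order(pts[, "y"])
  pts <- pts[o, , drop = FALSE]
  out <- matrix(0, n_corners, 2L, dimnames = list(NULL, c("x", "y")))
  for (rr in seq_len(rows)) {
    band <- pts[((rr - 1L) * cols + 1L):(rr * cols), , drop = FALSE]
    band <- band[order(band[, "x"]), , drop = FALSE]
    out[((rr - 1L) * cols + 1L):(rr * cols), ] <- band
  }
  out
}

# Top-n local maxima of a response map with a square suppression radius.
#' @noRd
local_peaks <- function(resp, radius, n) {
  found <- data.frame(r = integer(), c = integer(), value = numeric())
  work <- resp
  nr <- nrow(resp); nc <- ncol(resp)
  for (i in seq_len(n)) {
    j <- which.max(work)
    v <- work[j]
    if (!is.finite(v) || v <= 0) break
    r <- (j - 1L) %% nr + 1L
    c <- (j - 1L) %/% nr + 1L
    found <- rbind(found, data.frame(r = r, c = c, value = v))
    r0 <- max(1L, r - radius); r1 <- min(nr, r + radius)
    c0 <- max(1L, c - radius); c1 <- min(nc, c + radius)
    work[r0:r1, c0:c1] <- -Inf
  }
  found
}

# Least-squares similarity fit pa -> pb. Without rotation: isotropic scale +
# translation; with rotation: orthogonal Procrustes.
#' @noRd
fit_similarity <- function(pa, pb, allow_rotation = FALSE) {
  ma <- colMeans(pa); mb <- colMeans(pb)
  da <- sweep(pa, 2L, ma); db <- sweep(pb, 2L, mb)
  if (!allow_rotation) {
    s <- sum(da * db) / sum(da^2)
    A <- diag(2) * s
  } else {
    H <- crossprod(da, db)
    sv <- svd(H)
    R <- sv$v %*% t(sv$u)
    if (det(R) < 0) {
      sv$v[, 2] <- -sv$v[, 2]
      R <- sv$v %*% t(sv$u)
    }
    s <- sum((da %*% t(R)) * db) / sum(da^2)
    A <- s * R
  }
  t <- mb - A %*% ma
  m <- cbind(A, t)
  pred <- cbind(pa, 1) %*% t(m)
  rms <- sqrt(mean(rowSums((pred - pb)^2)))
  list(matrix = m, rms = rms, scale = s)
}

#' Rig-based scale adjustment between the visible and thermal streams
#'
#' Phase one of the two-phase registration: the checkerboard calibration rig is
#' located in a designated visible/thermal frame pair and a similarity
#' transform (isotropic scale + translation; rotation optional) is fitted by
#' least squares on the corresponding inner corners, absorbing the large
#' resolution disparity between the two cameras.
#'
#' @param rgb_frame Visible frame (numeric matrix; a single channel suffices).
#' @param thermal_frame Thermal frame (numeric matrix).
#' @param rig_spec Inner-corner grid `c(rows, cols)` of the rig.
#' @param allow_rotation Fit a rotation as well (default `FALSE`; the cameras
#'   are co-mounted and parallel).
#' @return An [affine_map()] with `provenance = "rig"` mapping visible to
#'   thermal pixels.
#' @export
scale_adjust_from_rig <- function(rgb_frame, thermal_frame, rig_spec = c(6L, 5L),
                                  allow_rotation = FALSE) {
  pa <- tryCatch(find_checkerboard_corners(rgb_frame, rig_spec),
                 rgbtresp_rig_error = function(e) {
                   stop_registration("rig", "checkerboard not found in the visible frame")
                 })
  pb <- tryCatch(find_checkerboard_corners(thermal_frame, rig_spec),
                 rgbtresp_rig_error = function(e) {
                   stop_registration("rig", "checkerboard not found in the thermal frame")
                 })
  fit <- fit_similarity(pa, pb, allow_rotation = allow_rotation)
  affine_map(fit$matrix, provenance = "rig",
             inlier_count = nrow(pa), rms_residual = fit$rms)
}
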