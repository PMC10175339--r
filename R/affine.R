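#' Affine map between visible and thermal pixel coordinates
#'
#' A 2x3 matrix mapping homogeneous 0-based pixel coordinates `(x, y, 1)`
#' (x = column, y = row) of one stream into another. The pipeline composes a
#' rig-based similarity (`provenance = "rig"`) with a phase-congruency
#' refinement (`"precise"`) into the map used for ROI transfer (`"composed"`).
#'
#' @param matrix Numeric 2x3 matrix `[[a, b, tx], [c, d, ty]]`.
#' @param provenance One of `"rig"`, `"precise"`, `"composed"`, `"identity"`,
#'   `"truth"`.
#' @param inlier_count Number of inlier correspondences behind the fit.
#' @param rms_residual Root-mean-square residual (target-frame pixels).
#' @return Object of class `affine_map`.
#' @export
affine_map <- function(matrix, provenance = "identity",
                       inlier_count = NA_integer_, rms_residual = NA_real_) {
  matrix <- base::matrix(as.numeric(matrix), 2L, 3L)
  det <- matrix[1, 1] * matrix[2, 2] - matrix[1, 2] * matrix[2, 1]
  if (!is.finite(det) || abs(det) <= 1e-8) {
    stop("affine map is singular (|det| <= 1e-8)", call. = FALSE)
  }
  structure(list(matrix = matrix, provenance = provenance,
                 inlier_count = as.integer(inlier_count),
                 rms_residual = rms_residual),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("<affine_map provenance=%s inliers=%s rms=%.4g>\n",
              x$provenance, x$inlier_count, x$rms_residual))
  print(x$matrix)
  invisible(x)
}

#' Identity affine map
#' @param provenance Provenance label for the map.
#' @return An [affine_map()] equal to the identity.
#' @export
affine_identity <- function(provenance = "identity") {
  affine_map(cbind(diag(2), c(0, 0)), provenance = provenance)
}

#' Similarity map (isotropic scale, rotation, translation)
#' @param scale Isotropic scale factor.
#' @param rotation Rotation (radians, counter-clockwise in pixel coords).
#' @param tx,ty Translation (target pixels).
#' @param provenance Provenance label.
#' @return An [affine_map()].
#' @export
affine_similarity <- function(scale = 1, rotation = 0, tx = 0, ty = 0,
                              provenance = "truth") {
  R <- matrix(c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2L, 2L)
  affine_map(cbind(scale * R, c(tx, ty)), provenance = provenance)
}

#' Apply an affine map to points
#' @param map An [affine_map()].
#' @param pts n x 2 matrix of 0-based `(x, y)` coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_affine <- function(map, pts) {
  pts <- base::matrix(as.numeric(pts), ncol = 2L)
  res <- cbind(pts, 1) %*% t(map$matrix)
  colnames(res) <- c("x", "y")
  res
}

#' Invert an affine map
#' @param map An [affine_map()].
#' @return The inverse [affine_map()].
#' @export
invert_affine <- function(map) {
  A <- map$matrix[, 1:2]
  t <- map$matrix[, 3]
  Ai <- solve(A)
  affine_map(cbind(Ai, -Ai %*% t), provenance = map$provenance)
}

#' Compose two affine maps
#'
#' Returns the map applying `inner` first, then `outer`.
#' @param outer,inner [affine_map()] objects.
#' @param provenance Provenance label of the composition.
#' @return An [affine_map()].
#' @export
compose_affine <- function(outer, inner, provenance = "composed") {
  A <- outer$matrix[, 1:2] %*% inner$matrix[, 1:2]
  t <- outer$matrix[, 1:2] %*% inner$matrix[, 3] + outer$matrix[, 3]
  affine_map(cbind(A, t), provenance = provenance,
             inlier_count = outer$inlier_count,
             rms_residual = outer$rms_residual)
}

# Least-squares affine fit mapping pa -> pb; NULL if degenerate (collinear).
#' @noRd
fit_affine_lsq <- function(pa, pb) {
  X <- cbind(pa, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) return(NULL)
  coef <- qr.coef(qrX, pb)          # 3 x 2
  m <- t(coef)[, c(1, 2, 3)]        # 2 x 3 (a b tx / c d ty)
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(det) || abs(det) <= 1e-8) return(NULL)
  m
}

#' Robust affine estimation by fast sample consensus
#'
#' Sample-and-refit estimator: minimal 3-point samples propose an affine map,
#' inliers within `inlier_tol` are collected, and the fit is re-estimated on
#' the growing consensus set until the inlier set is a fixed point. The best
#' consensus (most inliers, then lowest RMS) wins; the returned map is the
#' least-squares fit on its final inlier set.
#'
#' @param matches A [match_descriptors()] result (`match_set`).
#' @param kps_a,kps_b Keypoint tables (`x`, `y` columns, 0-based) the match
#'   indices refer to.
#' @param iterations Number of random minimal samples.
#' @param inlier_tol Inlier residual tolerance (target-frame pixels).
#' @param seed Integer seed; the estimator is deterministic given it.
#' @return An [affine_map()] with `provenance = "precise"`, `inlier_count`
#'   and `rms_residual` filled in.
#' @export
estimate_affine_fsc <- function(matches, kps_a, kps_b, iterations = 2000L,
                                inlier_tol = 2, seed = 1L) {
  pairs <- matches$pairs
  n <- nrow(pairs)
  if (is.null(pairs) || n < 3L) {
    stop_registration("consensus", "fewer than 3 matches; cannot fit an affine map")
  }
  pa <- cbind(kps_a$x[pairs$index_a], kps_a$y[pairs$index_a])
  pb <- cbind(kps_b$x[pairs$index_b], kps_b$y[pairs$index_b])

  resid <- function(m) {
    pred <- cbind(pa, 1) %*% t(m)
    sqrt(rowSums((pred - pb)^2))
  }

  best <- NULL
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 3L)
      m <- fit_affine_lsq(pa[s, , drop = FALSE], pb[s, , drop = FALSE])
      if (is.null(m)) next
      inl <- which(resid(m) <= inlier_tol)
      if (length(inl) < 3L) next
      # refit on the consensus set until it stabilises
      repeat {
        m2 <- fit_affine_lsq(pa[inl, , drop = FALSE], pb[inl, , drop = FALSE])
        if (is.null(m2)) break
        inl2 <- which(resid(m2) <= inlier_tol)
        if (length(inl2) < 3L) break
        if (length(inl2) == length(inl) && all(inl2 == inl)) {
          m <- m2
          break
        }
        inl <- inl2
        m <- m2
      }
      r <- resid(m)[inl]
      rms <- sqrt(mean(r^2))
      if (is.null(best) || length(inl) > best$count ||
          (length(inl) == best$count && rms < best$rms)) {
        best <- list(m = m, count = length(inl), rms = rms, inl = inl)
      }
      if (best$count == n && best$rms < 1e-9) break
    }
  })
  if (is.null(best)) {
    stop_registration("consensus", "no non-degenerate consensus set found")
  }
  affine_map(best$m, provenance = "precise",
             inlier_count = best$count, rms_residual = best$rms)
}

#' Map a visible-frame ROI into the thermal frame
#'
#' Maps the four corners of the (half-open) box, takes their axis-aligned
#' bounding box, rounds it outward to integer pixels and clips it to the
#' thermal frame. A box falling fully outside is returned empty and flagged.
#'
#' @param roi An [roi_box()] in visible coordinates.
#' @param map An [affine_map()] from visible to thermal pixels.
#' @param thermal_shape Thermal frame dimensions `c(nrow, ncol)`.
#' @return An [roi_box()] in thermal coordinates (possibly empty).
#' @export
map_roi <- function(roi, map, thermal_shape) {
  corners <- rbind(c(roi$bx, roi$by),
                   c(roi$bx + roi$w, roi$by),
                   c(roi$bx, roi$by + roi$h),
                   c(roi$bx + roi$w, roi$by + roi$h))
  p <- apply_affine(map, corners)
  x0 <- floor(min(p[, 1])); x1 <- ceiling(max(p[, 1]))
  y0 <- floor(min(p[, 2])); y1 <- ceiling(max(p[, 2]))
  W <- thermal_shape[2]; H <- thermal_shape[1]
  x0c <- max(x0, 0); y0c <- max(y0, 0)
  x1c <- min(x1, W); y1c <- min(y1, H)
  if (x1c - x0c <= 0 || y1c - y0c <= 0) {
    return(roi_box(0, 0, 0, 0, coord_frame = "thermal", empty = TRUE,
                   frame_id = roi$frame_id))
  }
  roi_box(x0c, y0c, x1c - x0c, y1c - y0c, coord_frame = "thermal",
          frame_id = roi$frame_id, eta = roi$eta, omega = roi$omega)
}

#' Serialize / deserialize an affine map as JSON
#' @param map An [affine_map()].
#' @param path Output / input file path.
#' @return `write_affine_json` returns `path` invisibly; `read_affine_json`
#'   returns an [affine_map()].
#' @export
write_affine_json <- function(map, path) {
  obj <- list(matrix = unclass(map$matrix), provenance = map$provenance,
              inlier_count = map$inlier_count, rms_residual = map$rms_residual)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$matrix  # written row-major; simplifyVector restores a 2x3 matrix
  affine_map(base::matrix(c(m[1, 1], m[2, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3]), 2L, 3L),
             provenance = obj$provenance %||% "composed",
             inlier_count = obj$inlier_count %||% NA_integer_,
             rms_residual = obj$rms_residual %||% NA_real_)
}

# Classed registration failure carrying the failing stage.
#' @noRd
stop_registration <- function(stage, msg) {
  cond <- structure(class = c("rgbtresp_registration_error", "error", "condition"),
                    list(message = sprintf("registration failed at stage '%s': %s",
                                           stage, msg),
                         call = NULL, stage = stage))
  stop(cond)
}
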