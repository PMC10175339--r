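#' Five-point facial landmarks
#'
#' Eye centres, nose tip and mouth corners in 0-based visible-frame pixel
#' coordinates, plus a detection confidence in `[0, 1]`.
#'
#' @param left_eye,right_eye,nose_tip,mouth_left,mouth_right Numeric `(x, y)`.
#' @param confidence Detection confidence in `[0, 1]`.
#' @return Object of class `landmarks5`.
#' @export
landmarks5 <- function(left_eye, right_eye, nose_tip, mouth_left, mouth_right,
                       confidence = 1) {
  pt <- function(p) {
    stopifnot(length(p) == 2, all(is.finite(p)))
    as.numeric(p)
  }
  structure(list(left_eye = pt(left_eye), right_eye = pt(right_eye),
                 nose_tip = pt(nose_tip), mouth_left = pt(mouth_left),
                 mouth_right = pt(mouth_right),
                 confidence = as.numeric(confidence)),
            class = "landmarks5")
}

#' Rectangular region of interest
#'
#' A `[bx, by, w, h]` rectangle, 0-based and half-open in both axes, in a named
#' coordinate frame. Landmark-derived nostril boxes carry the half-width
#' `omega` and the unit height `eta` (so `w = 2*omega`, `h = 3*eta` before
#' clipping).
#'
#' @param bx,by Top-left corner (pixels, 0-based).
#' @param w,h Width and height (pixels).
#' @param coord_frame `"visible"` or `"thermal"`.
#' @param frame_id Frame index the box belongs to.
#' @param eta,omega Landmark geometry parameters (pixels), if applicable.
#' @param empty Flag for a box clipped to nothing.
#' @return Object of class `roi_box`.
#' @export
roi_box <- function(bx, by, w, h, coord_frame = "visible", frame_id = NA_integer_,
                    eta = NA_real_, omega = NA_real_, empty = FALSE) {
  structure(list(bx = as.numeric(bx), by = as.numeric(by),
                 w = as.numeric(w), h = as.numeric(h),
                 coord_frame = coord_frame, frame_id = frame_id,
                 eta = eta, omega = omega, empty = isTRUE(empty)),
            class = "roi_box")
}

#' Nostril ROI from facial landmarks
#'
#' The nostril rectangle is anchored at the nose tip: with
#' `eta = round(sqrt((mlx - nx)^2 + (mly - ny)^2) / 4)` and
#' `omega = round(|mlx - mrx| / 2)`, the ROI is
#' `[nx - omega, ny - eta, 2*omega, 3*eta]`. Rounding is round-half-to-even
#' (base R `round`). The box is clipped to the frame when `frame_shape` is
#' given; degenerate landmark geometry (`eta` or `omega` of zero) is an error.
#'
#' @param lm A [landmarks5()] object.
#' @param frame_shape Optional `c(nrow, ncol)` to clip against.
#' @param frame_id Frame index recorded on the box.
#' @return An [roi_box()] in visible coordinates.
#' @export
roi_from_landmarks <- function(lm, frame_shape = NULL, frame_id = NA_integer_) {
  stopifnot(inherits(lm, "landmarks5"))
  nx <- lm$nose_tip[1]; ny <- lm$nose_tip[2]
  mlx <- lm$mouth_left[1]; mly <- lm$mouth_left[2]
  mrx <- lm$mouth_right[1]
  eta <- round(sqrt((mlx - nx)^2 + (mly - ny)^2) / 4)
  omega <- round(abs(mlx - mrx) / 2)
  if (eta == 0 || omega == 0) {
    stop("degenerate landmark geometry: eta or omega is zero", call. = FALSE)
  }
  bx <- nx - omega; by <- ny - eta; w <- 2 * omega; h <- 3 * eta
  if (!is.null(frame_shape)) {
    x1 <- min(bx + w, frame_shape[2]); y1 <- min(by + h, frame_shape[1])
    bx <- max(bx, 0); by <- max(by, 0)
    w <- x1 - bx; h <- y1 - by
    if (w <= 0 || h <= 0) {
      return(roi_box(0, 0, 0, 0, frame_id = frame_id, eta = eta, omega = omega,
                     empty = TRUE))
    }
  }
  roi_box(bx, by, w, h, frame_id = frame_id, eta = eta, omega = omega)
}

#' Synthetic-fiducial landmark detector
#'
#' Landmark detector for the bundled synthetic scene generator, which plants
#' five plus-shaped fiducial markers whose identity is encoded by intensity
#' level (this is a synthetic stand-in for a pretrained face-landmark network,
#' which is deliberately out of scope; see [detect_landmarks()] for the
#' detector contract an external adapter must satisfy).
#'
#' @param levels Named intensity levels of the five markers.
#' @param tol Maximum |pixel - level| for a pixel to count as marker material;
#'   `NULL` (default) uses half the minimum level spacing, so each candidate
#'   pixel is assigned to its nearest level.
#' @param min_pixels Minimum marker pixels per landmark for full confidence
#'   (the fiducial cross has 9; partial occlusion lowers confidence).
#' @return A detector function `frame -> list(landmarks, confidence)` usable
#'   with [detect_landmarks()].
#' @export
make_fiducial_detector <- function(levels = fiducial_levels(), tol = NULL,
                                   min_pixels = 9L) {
  lv <- unlist(levels)
  if (is.null(tol)) tol <- min(diff(sort(lv))) / 2
  force(levels); force(min_pixels)
  function(frame) {
    cand <- which(frame > min(lv) - tol)
    if (length(cand) == 0L) return(list(landmarks = NULL, confidence = 0))
    nr <- nrow(frame)
    vals <- frame[cand]
    xs <- (cand - 1L) %/% nr
    ys <- (cand - 1L) %% nr
    # nearest-level classification within the tolerance
    nearest <- vapply(vals, function(v) which.min(abs(lv - v)), 0L)
    indist <- abs(vals - lv[nearest]) < tol
    pts <- list(); conf <- numeric(0)
    for (j in seq_along(levels)) {
      nm <- names(levels)[j]
      sel <- indist & nearest == j
      if (!any(sel)) return(list(landmarks = NULL, confidence = 0))
      pts[[nm]] <- c(mean(xs[sel]), mean(ys[sel]))
      conf <- c(conf, min(1, sum(sel) / min_pixels))
    }
    list(landmarks = landmarks5(pts$left_eye, pts$right_eye, pts$nose_tip,
                                pts$mouth_left, pts$mouth_right,
                                confidence = min(conf)),
         confidence = min(conf))
  }
}

#' Fiducial intensity coding
#'
#' Intensity levels (on the `[0, 1]` visible scale) identifying each planted
#' landmark marker in synthetic scenes.
#' @return Named list of five levels.
#' @export
fiducial_levels <- function() {
  list(left_eye = 0.96, right_eye = 0.97, nose_tip = 0.98,
       mouth_left = 0.99, mouth_right = 1.0)
}

#' Run a landmark detector on a frame
#'
#' Applies a detector satisfying the contract
#' `frame -> list(landmarks = landmarks5 | NULL, confidence = numeric)` and
#' derives the detection status flag: `d_s` is `TRUE` iff landmarks were
#' returned with confidence at or above `conf_threshold`. Detector exceptions
#' are caught and reported as failed detection.
#'
#' @param frame Numeric matrix.
#' @param detector Detector function (e.g. [make_fiducial_detector()] or an
#'   adapter around an external pretrained face-landmark model).
#' @param conf_threshold Minimum confidence for a positive detection.
#' @return List with `landmarks` ([landmarks5()] or `NULL`) and logical `d_s`.
#' @export
detect_landmarks <- function(frame, detector, conf_threshold = 0.6) {
  res <- tryCatch(detector(frame), error = function(e) {
    list(landmarks = NULL, confidence = 0)
  })
  ok <- !is.null(res$landmarks) && isTRUE(res$confidence >= conf_threshold)
  list(landmarks = if (ok) res$landmarks else NULL, d_s = ok)
}
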