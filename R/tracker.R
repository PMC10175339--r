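# Normalised-cross-correlation template tracker with exponential template update.

#' Tracker configuration
#'
#' @param search_radius Search radius (pixels) around the previous box.
#' @param learning_rate Exponential template-update rate in `[0, 1]`.
#' @param quality_threshold Correlation peak below which tracking is declared
#'   failed (`t_s = FALSE`).
#' @param max_template_px Templates larger than this are correlated on a
#'   strided subsample for speed (the box itself keeps full resolution).
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(search_radius = 8L, learning_rate = 0.075,
                           quality_threshold = 0.5, max_template_px = 2500L) {
  structure(list(search_radius = as.integer(search_radius),
                 learning_rate = learning_rate,
                 quality_threshold = quality_threshold,
                 max_template_px = as.integer(max_template_px)),
            class = "tracker_config")
}

#' Initialise the correlation tracker
#'
#' @param frame Numeric matrix (visible frame).
#' @param box An [roi_box()] giving the target.
#' @param config A [tracker_config()].
#' @return A `ncc_tracker` state object.
#' @export
tracker_init <- function(frame, box, config = tracker_config()) {
  h <- round(box$h); w <- round(box$w)
  by <- round(box$by); bx <- round(box$bx)
  stopifnot(h >= 2, w >= 2, by >= 0, bx >= 0,
            by + h <= nrow(frame), bx + w <= ncol(frame))
  template <- frame[(by + 1):(by + h), (bx + 1):(bx + w), drop = FALSE]
  stride <- if (h * w > config$max_template_px) {
    ceiling(sqrt(h * w / config$max_template_px))
  } else 1L
  structure(list(template = template, bx = bx, by = by, w = w, h = h,
                 stride = stride, config = config, initialized = TRUE),
            class = "ncc_tracker")
}

#' Advance the tracker one frame
#'
#' Searches a window of `search_radius` pixels around the previous box for the
#' offset maximising the Pearson correlation between the template and the
#' image patch; the peak correlation is the tracker quality, and the template
#' is blended toward the new patch (`learning_rate`) on success.
#'
#' @param tracker State from [tracker_init()] (or `NULL` / uninitialised, which
#'   yields `t_s = FALSE`).
#' @param frame Numeric matrix.
#' @return List: updated `tracker`, `box` ([roi_box()] or `NULL`), `quality`
#'   (peak correlation), and logical `t_s`.
#' @export
tracker_step <- function(tracker, frame) {
  if (is.null(tracker) || !isTRUE(tracker$initialized)) {
    return(list(tracker = tracker, box = NULL, quality = 0, t_s = FALSE))
  }
  cfg <- tracker$config
  h <- tracker$h; w <- tracker$w
  nr <- nrow(frame); nc <- ncol(frame)
  ri <- seq(1L, h, by = tracker$stride)
  ci <- seq(1L, w, by = tracker$stride)
  tv <- as.vector(tracker$template[ri, ci, drop = FALSE])
  tv <- tv - mean(tv)
  tnorm <- sqrt(sum(tv^2))
  best_q <- -Inf; best_dx <- 0L; best_dy <- 0L
  r <- cfg$search_radius
  for (dy in -r:r) {
    y0 <- tracker$by + dy
    if (y0 < 0L || y0 + h > nr) next
    for (dx in -r:r) {
      x0 <- tracker$bx + dx
      if (x0 < 0L || x0 + w > nc) next
      pv <- as.vector(frame[y0 + ri, x0 + ci, drop = FALSE])
      pv <- pv - mean(pv)
      pn <- sqrt(sum(pv^2))
      q <- if (tnorm <= 0 || pn <= 0) 0 else sum(tv * pv) / (tnorm * pn)
      if (q > best_q) {
        best_q <- q; best_dx <- dx; best_dy <- dy
      }
    }
  }
  if (!is.finite(best_q)) {
    return(list(tracker = tracker, box = NULL, quality = 0, t_s = FALSE))
  }
  t_s <- best_q >= cfg$quality_threshold
  if (t_s) {
    tracker$bx <- tracker$bx + best_dx
    tracker$by <- tracker$by + best_dy
    patch <- frame[(tracker$by + 1):(tracker$by + h),
                   (tracker$bx + 1):(tracker$bx + w), drop = FALSE]
    lr <- cfg$learning_rate
    tracker$template <- (1 - lr) * tracker$template + lr * patch
  }
  box <- roi_box(tracker$bx, tracker$by, w, h, coord_frame = "visible")
  list(tracker = tracker, box = box, quality = best_q, t_s = t_s)
}
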