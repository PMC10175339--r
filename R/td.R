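# Tracking-by-detection selection operator and per-frame ROI logging.

#' Initial tracking-by-detection state
#'
#' The loop starts in detection mode: the first frame always runs the detector
#' and, on success, initialises the tracker with the detected ROI.
#'
#' @param tracker_cfg A [tracker_config()].
#' @param conf_threshold Detection confidence threshold.
#' @param frame_shape Visible frame dimensions `c(nrow, ncol)` (for clipping).
#' @return A `td_state` object.
#' @export
td_init <- function(tracker_cfg = tracker_config(), conf_threshold = 0.6,
                    frame_shape = NULL) {
  structure(list(mode = "detecting", tracker = NULL,
                 tracker_cfg = tracker_cfg, conf_threshold = conf_threshold,
                 frame_shape = frame_shape, current_roi = NULL,
                 t_s = FALSE, d_s = FALSE, tracker_quality = 0,
                 log = list()),
            class = "td_state")
}

#' One step of the tracking-by-detection selection operator
#'
#' The detector runs every frame (yielding `d_s`); the tracker runs only in
#' tracking mode (yielding `t_s`). The selection operator enables tracking in
#' the successive frame only when both `t_s` and `d_s` are `TRUE`; when either
#' is `FALSE` tracking is disabled and the ROI comes from detection until a
#' successful re-detection reinitialises the tracker. Every frame is logged
#' with its ROI or `NA` when neither source produced one.
#'
#' @param state A `td_state` from [td_init()] / previous steps.
#' @param frame Visible frame (numeric matrix).
#' @param detector Landmark detector (see [detect_landmarks()]).
#' @param frame_id Frame index used in the log.
#' @return The updated `td_state`.
#' @export
td_step <- function(state, frame, detector, frame_id = length(state$log) + 1L) {
  shape <- state$frame_shape %||% dim(frame)
  det <- detect_landmarks(frame, detector, state$conf_threshold)
  d_s <- det$d_s
  roi_det <- NULL
  if (d_s) {
    roi_det <- tryCatch(
      roi_from_landmarks(det$landmarks, frame_shape = shape, frame_id = frame_id),
      error = function(e) NULL)
    # boxes degenerating below 2x2 px after clipping count as detection failure
    if (is.null(roi_det) || roi_det$empty || roi_det$w < 2 || roi_det$h < 2) {
      d_s <- FALSE
      roi_det <- NULL
    }
  }

  t_s <- FALSE; quality <- 0; roi_trk <- NULL
  if (state$mode == "tracking") {
    ts <- tracker_step(state$tracker, frame)
    state$tracker <- ts$tracker
    t_s <- ts$t_s; quality <- ts$quality
    if (t_s) roi_trk <- ts$box
  }

  # the tracked box is the ROI only while tracking stays enabled (t_s & d_s);
  # otherwise the ROI comes from detection, or is none
  roi <- if (state$mode == "tracking" && t_s && d_s) roi_trk else roi_det
  if (!is.null(roi)) roi$frame_id <- frame_id

  if (state$mode == "tracking") {
    next_mode <- if (t_s && d_s) "tracking" else "detecting"
    if (next_mode == "detecting") state$tracker <- NULL
  } else {
    if (d_s) {
      state$tracker <- tracker_init(frame, roi_det, state$tracker_cfg)
      next_mode <- "tracking"
    } else {
      next_mode <- "detecting"
    }
  }

  state$log[[length(state$log) + 1L]] <- list(
    frame_id = frame_id, mode = state$mode,
    bx = if (is.null(roi)) NA_real_ else roi$bx,
    by = if (is.null(roi)) NA_real_ else roi$by,
    w = if (is.null(roi)) NA_real_ else roi$w,
    h = if (is.null(roi)) NA_real_ else roi$h,
    t_s = t_s, d_s = d_s, quality = quality)
  state$mode <- next_mode
  state$current_roi <- roi
  state$t_s <- t_s; state$d_s <- d_s; state$tracker_quality <- quality
  state
}

#' Run the tracking-by-detection loop over a sequence
#'
#' @param frame_fn Function `i -> matrix` yielding visible frame `i`.
#' @param n_frames Number of frames.
#' @param detector Landmark detector function.
#' @param tracker_cfg A [tracker_config()].
#' @param conf_threshold Detection confidence threshold.
#' @param progress Print a progress note every `progress` frames (0 = quiet).
#' @return A tibble ROI log: `frame_id`, `mode`, `bx`, `by`, `w`, `h`, `t_s`,
#'   `d_s`, `quality` (one row per frame; `NA` box when undetected).
#' @export
run_td <- function(frame_fn, n_frames, detector,
                   tracker_cfg = tracker_config(), conf_threshold = 0.6,
                   progress = 0L) {
  state <- td_init(tracker_cfg, conf_threshold)
  for (i in seq_len(n_frames)) {
    state <- td_step(state, frame_fn(i), detector, frame_id = i)
    if (progress > 0L && i %% progress == 0L) {
      message(sprintf("td: frame %d/%d (%s)", i, n_frames, state$mode))
    }
  }
  td_log(state)
}

#' Extract the ROI log of a tracking-by-detection state
#' @param state A `td_state`.
#' @return Tibble log (see [run_td()]).
#' @export
td_log <- function(state) {
  stopifnot(inherits(state, "td_state"))
  dplyr::bind_rows(lapply(state$log, tibble::as_tibble))
}

#' ROI success rate
#'
#' Percentage of frames with a valid ROI:
#' `100 * detected_frames / total_frames`.
#'
#' @param log ROI log tibble (from [run_td()] / [td_log()]).
#' @return Percentage in `[0, 100]`.
#' @export
roi_success_rate <- function(log) {
  if (is.null(log) || nrow(log) == 0L) {
    stop("empty ROI log: no frames to score", call. = FALSE)
  }
  100 * sum(!is.na(log$bx)) / nrow(log)
}

#' Write / read a per-frame ROI log as CSV
#' @param log ROI log tibble.
#' @param path File path.
#' @return `write_roi_log` returns `path` invisibly; `read_roi_log` the tibble.
#' @export
write_roi_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_log
#' @export
read_roi_log <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
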