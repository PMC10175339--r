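# I/O, configuration and the end-to-end pipeline.

#' Write a thermal frame stack as 16-bit TIFF
#'
#' Frames are quantised at `scale` degC per count (default 0.01) relative to
#' `offset` and written as one 16-bit grayscale TIFF per frame
#' (`frame_000001.tif`, ...), with a `meta.json` sidecar recording the scale,
#' offset and frame rate.
#'
#' @param frames Function `i -> matrix` or list of matrices (degC).
#' @param n_frames Number of frames (required when `frames` is a function).
#' @param dir Output directory (created if missing).
#' @param fps Frame rate recorded in the sidecar.
#' @param scale Quantisation step (degC per count).
#' @param offset Temperature of count 0 (degC).
#' @return `dir`, invisibly.
#' @export
write_thermal_stack <- function(frames, dir, n_frames = NULL, fps = 30,
                                scale = 0.01, offset = 0) {
  frame_fn <- if (is.function(frames)) frames else function(i) frames[[i]]
  if (is.null(n_frames)) n_frames <- length(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_frames)) {
    counts <- pmin(pmax(round((frame_fn(i) - offset) / scale), 0), 65535)
    tiff::writeTIFF(counts / 65535, file.path(dir, sprintf("frame_%06d.tif", i)),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(list(modality = "thermal", scale = scale, offset = offset,
                            fps = fps, n_frames = n_frames),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a visible frame sequence as PNG
#'
#' Frames (values in `[0, 1]`) are written as 8-bit grayscale PNGs with a
#' `meta.json` sidecar.
#'
#' @inheritParams write_thermal_stack
#' @return `dir`, invisibly.
#' @export
write_visible_frames <- function(frames, dir, n_frames = NULL, fps = 30) {
  frame_fn <- if (is.function(frames)) frames else function(i) frames[[i]]
  if (is.null(n_frames)) n_frames <- length(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_frames)) {
    png::writePNG(pmin(pmax(frame_fn(i), 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(list(modality = "visible", fps = fps, n_frames = n_frames),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame sequence from a directory
#'
#' Accepts a directory of `frame_NNNNNN.tif` / `.png` files with an optional
#' `meta.json` sidecar. Frame numbering must be gap-free; thermal stacks with
#' radiometric metadata are rescaled to degC. Frames are loaded lazily.
#'
#' @param path Directory path.
#' @param modality `"thermal"` or `"visible"` (checked against the sidecar
#'   when present).
#' @param fps Frame rate; overrides the sidecar when given.
#' @return A frame-stream list: `frame(i)`, `n_frames`, `fps`, `shape`,
#'   `modality`.
#' @export
read_sequence <- function(path, modality = c("thermal", "visible"), fps = NULL) {
  modality <- match.arg(modality)
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path), call. = FALSE)
  files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.(tif|tiff|png)$"))
  if (length(files) == 0L) stop(sprintf("no frames found in %s", path), call. = FALSE)
  nums <- as.integer(sub("^frame_([0-9]+)\\..*$", "\\1", files))
  expected <- seq.int(min(nums), length.out = length(nums))
  if (!all(nums == expected)) {
    missing <- setdiff(seq.int(min(nums), max(nums)), nums)
    stop(sprintf("missing frame index %d in %s", missing[1], path), call. = FALSE)
  }
  meta <- list()
  mpath <- file.path(path, "meta.json")
  if (file.exists(mpath)) meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!is.null(meta$modality) && !identical(meta$modality, modality)) {
    stop(sprintf("sequence at %s is %s, not %s", path, meta$modality, modality),
         call. = FALSE)
  }
  fps <- fps %||% meta$fps %||% 30
  scale <- meta$scale %||% 1
  offset <- meta$offset %||% 0
  load_one <- function(i) {
    f <- file.path(path, files[i])
    if (grepl("png$", f)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    } else {
      img <- tiff::readTIFF(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      if (identical(meta$modality, "thermal")) img * 65535 * scale + offset else img
    }
  }
  first <- load_one(1L)
  shp <- dim(first)
  frame <- function(i) {
    img <- load_one(i)
    if (!all(dim(img) == shp)) {
      stop(sprintf("frame %d has shape %dx%d, expected %dx%d",
                   i, nrow(img), ncol(img), shp[1], shp[2]), call. = FALSE)
    }
    img
  }
  list(frame = frame, n_frames = length(files), fps = fps, shape = shp,
       modality = modality)
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Band defaults follow the
#' population (`[0.1, 0.85]` Hz adult, `[0.5, 1.5]` Hz neonate); windowing
#' defaults to 30 s windows stepped by 20 s.
#'
#' @param population `"adult"` or `"neonate"`.
#' @param window_s,step_s Analysis window and step (seconds).
#' @param band A [band_config()]; `NULL` uses the population default.
#' @param register A [register_params()].
#' @param tracker A [tracker_config()].
#' @param conf_threshold Detection confidence threshold.
#' @param rig_dims Inner-corner grid of the calibration rig.
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(population = c("neonate", "adult"), window_s = 30,
                            step_s = 20, band = NULL,
                            register = register_params(),
                            tracker = tracker_config(), conf_threshold = 0.6,
                            rig_dims = c(6L, 5L), seed = 1L, out_dir = NULL) {
  population <- match.arg(population)
  band <- band %||% band_config(population)
  stopifnot(window_s > 0, step_s > 0, inherits(band, "band_config"))
  structure(list(population = population, window_s = window_s, step_s = step_s,
                 band = band, register = register, tracker = tracker,
                 conf_threshold = conf_threshold, rig_dims = rig_dims,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `population`, `window_s`, `step_s`,
#' `band: {low_hz, high_hz, order}`, `seed`, `rig_dims`, `conf_threshold`,
#' `out_dir`, and nested `register` / `tracker` parameter blocks.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  band <- NULL
  if (!is.null(y$band)) {
    band <- band_config(y$population %||% "neonate",
                        low_hz = y$band$low_hz, high_hz = y$band$high_hz,
                        order = y$band$order %||% 2L)
  }
  reg <- do.call(register_params, y$register %||% list())
  trk <- do.call(tracker_config, y$tracker %||% list())
  pipeline_config(population = y$population %||% "neonate",
                  window_s = y$window_s %||% 30, step_s = y$step_s %||% 20,
                  band = band, register = reg, tracker = trk,
                  conf_threshold = y$conf_threshold %||% 0.6,
                  rig_dims = unlist(y$rig_dims %||% c(6L, 5L)),
                  seed = y$seed %||% 1L, out_dir = y$out_dir)
}

#' Estimate RR from an RGB-T sequence with a known registration map
#'
#' The core per-recording chain: tracking-by-detection ROI selection on the
#' visible stream, linear mapping of each ROI into the thermal stream, mean-ROI
#' signal extraction, and sliding-window chirp-Z RR estimation.
#'
#' @param seq An `rgbt_sequence` (see [generate_scene()]) or a list with
#'   `rgb_frame(i)`, `thermal_frame(i)`, `n_frames`, `fps`, `thermal_shape`.
#' @param map Visible-to-thermal [affine_map()].
#' @param config A [pipeline_config()].
#' @param detector Landmark detector (defaults to the synthetic-fiducial
#'   detector).
#' @return List: `rr` (`rr_series`), `roi_log`, `signal` (the raw
#'   [resp_signal()]), `map`.
#' @export
estimate_rr_pipeline <- function(seq, map, config = pipeline_config(),
                                 detector = make_fiducial_detector()) {
  log <- run_td(seq$rgb_frame, seq$n_frames, detector,
                tracker_cfg = config$tracker,
                conf_threshold = config$conf_threshold)
  rois <- lapply(seq_len(nrow(log)), function(i) {
    if (is.na(log$bx[i])) return(NULL)
    map_roi(roi_box(log$bx[i], log$by[i], log$w[i], log$h[i], frame_id = i),
            map, seq$thermal_shape)
  })
  sig <- extract_raw_signal(seq$thermal_frame, rois, fs = seq$fps)
  rr <- sliding_rr(sig, config$band, window_s = config$window_s,
                   step_s = config$step_s)
  list(rr = rr, roi_log = log, signal = sig, map = map)
}

#' Run the full pipeline
#'
#' Executes the complete chain on an RGB-T recording: rig-based scale
#' adjustment (from a designated calibration frame pair), phase-congruency
#' refinement on the first post-calibration frame pair, tracking-by-detection
#' ROI selection, ROI mapping, signal extraction, sliding-window RR
#' estimation, and (when a reference signal is supplied) agreement metrics.
#' Outputs are written to `config$out_dir` when set (`rr.csv`, `roi_log.csv`,
#' `map.json`, `metrics.json`).
#'
#' @param seq An `rgbt_sequence`.
#' @param config A [pipeline_config()].
#' @param rig_pair Optional list with `rgb` and `thermal` calibration frames;
#'   `NULL` skips the rig phase (then `map` must be given).
#' @param map Optional precomputed [affine_map()]; skips registration.
#' @param reference Optional reference [resp_signal()] (e.g. a 10 Hz
#'   respiration-belt force series) for the metrics report.
#' @param detector Landmark detector.
#' @return List: `rr`, `roi_log`, `signal`, `map`, and `metrics` (or `NULL`).
#' @export
run_pipeline <- function(seq, config = pipeline_config(), rig_pair = NULL,
                         map = NULL, reference = NULL,
                         detector = make_fiducial_detector()) {
  if (is.null(map)) {
    rig_map <- NULL
    if (!is.null(rig_pair)) {
      rig_map <- scale_adjust_from_rig(rig_pair$rgb, rig_pair$thermal,
                                       rig_spec = config$rig_dims)
    }
    map <- register_rgbt(seq$rgb_frame(1L), seq$thermal_frame(1L),
                         rig_map = rig_map, params = config$register)
  }
  res <- estimate_rr_pipeline(seq, map, config, detector = detector)
  metrics <- NULL
  if (!is.null(reference)) {
    ref_rr <- reference_rr_from_belt(reference, config$band,
                                     window_s = config$window_s,
                                     step_s = config$step_s)
    metrics <- metrics_report(res$rr, ref_rr, roi_log = res$roi_log)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rr_csv(res$rr, file.path(config$out_dir, "rr.csv"))
    write_roi_log(res$roi_log, file.path(config$out_dir, "roi_log.csv"))
    write_affine_json(map, file.path(config$out_dir, "map.json"))
    if (!is.null(metrics)) {
      write_metrics_json(metrics, file.path(config$out_dir, "metrics.json"))
    }
  }
  c(res, list(metrics = metrics))
}
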