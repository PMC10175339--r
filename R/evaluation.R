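# Agreement metrics between estimated and reference RR series.

#' Average absolute error and its standard deviation
#'
#' With absolute errors `AE(k) = |BR_m(k) - BR_r(k)|` over the `N` paired
#' measurements, `AAE` is their mean and `SDE` their sample standard deviation
#' (`N - 1` denominator).
#'
#' @param measured,reference Numeric RR vectors (bpm) of equal length.
#' @return Named list `aae`, `sde`, `n`.
#' @export
aae_sde <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("measured and reference series differ in length", call. = FALSE)
  }
  n <- length(measured)
  if (n < 2L) stop("need at least 2 measurements for SDE", call. = FALSE)
  ae <- abs(measured - reference)
  list(aae = mean(ae), sde = stats::sd(ae), n = n)
}

#' Bland-Altman agreement statistics
#'
#' Differences `measured - reference`, their mean, and the 95% limits of
#' agreement `mean +/- 1.96 * sd` (sample standard deviation).
#'
#' @param measured,reference Numeric RR vectors (bpm) of equal length (N >= 2).
#' @return List: `mean_diff`, `loa_low`, `loa_high`, and a tibble `points`
#'   with per-pair `mean` and `diff`.
#' @export
bland_altman <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("measured and reference series differ in length", call. = FALSE)
  }
  if (length(measured) < 2L) stop("need at least 2 measurements", call. = FALSE)
  d <- measured - reference
  md <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
       points = tibble::tibble(mean = (measured + reference) / 2, diff = d))
}

#' Pearson correlation between measured and reference RR
#' @param measured,reference Numeric vectors (N >= 3, both non-constant).
#' @return The sample correlation coefficient.
#' @export
pearson_r <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("measured and reference series differ in length", call. = FALSE)
  }
  if (length(measured) < 3L) stop("need at least 3 measurements", call. = FALSE)
  if (stats::sd(measured) == 0 || stats::sd(reference) == 0) stop_flat_signal()
  stats::cor(measured, reference)
}

#' Reference RR from a respiration-belt force signal
#'
#' Applies the same windowing, conditioning chain and chirp-Z estimation as
#' the thermal pipeline to the belt force signal at its native sampling rate
#' (typically 10 Hz for force-sensing belts), producing a window-aligned RR
#' series. (Deriving the reference spectrally, rather than by breath counting,
#' is this package's documented choice.)
#'
#' @param belt_signal A [resp_signal()] (force series, e.g. fs = 10).
#' @param band A [band_config()].
#' @param window_s,step_s Window length and step (seconds); must match the
#'   thermal pipeline configuration.
#' @param ... Passed to [sliding_rr()].
#' @return An `rr_series` tibble.
#' @export
reference_rr_from_belt <- function(belt_signal, band, window_s = 30,
                                   step_s = 20, ...) {
  stopifnot(inherits(belt_signal, "resp_signal"))
  if (band$high_hz >= belt_signal$fs / 2) {
    stop("belt sampling rate too low for the configured band", call. = FALSE)
  }
  sliding_rr(belt_signal, band, window_s = window_s, step_s = step_s, ...)
}

#' Agreement report between measured and reference RR series
#'
#' Aligns the two series by window start time (both must use the same
#' window/step configuration) and computes AAE, SDE, Pearson correlation and
#' Bland-Altman statistics, plus the ROI success rate when a log is supplied.
#'
#' @param measured,reference `rr_series` tibbles.
#' @param roi_log Optional ROI log tibble for the success-rate field.
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(measured, reference, roi_log = NULL) {
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(measured), "window_start", m = "rr_bpm"),
    dplyr::select(tibble::as_tibble(reference), "window_start", r = "rr_bpm"),
    by = "window_start")
  if (nrow(j) < 2L) stop("fewer than 2 aligned windows", call. = FALSE)
  err <- aae_sde(j$m, j$r)
  ba <- bland_altman(j$m, j$r)
  r <- if (nrow(j) >= 3L && stats::sd(j$m) > 0 && stats::sd(j$r) > 0) {
    stats::cor(j$m, j$r)
  } else NA_real_
  structure(list(aae = err$aae, sde = err$sde, n_measurements = err$n,
                 pearson_r = r, bland_mean_diff = ba$mean_diff,
                 bland_loa_low = ba$loa_low, bland_loa_high = ba$loa_high,
                 roi_success_rate = if (is.null(roi_log)) NA_real_
                 else roi_success_rate(roi_log),
                 points = ba$points, aligned = j),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metrics_report N=%d>\n  AAE %.4f bpm | SDE %.4f bpm | r %.4f\n",
    "  Bland-Altman %.3f bpm [%.3f, %.3f]\n  ROI success rate %s\n"),
    x$n_measurements, x$aae, x$sde, x$pearson_r,
    x$bland_mean_diff, x$bland_loa_low, x$bland_loa_high,
    if (is.na(x$roi_success_rate)) "NA" else sprintf("%.2f%%", x$roi_success_rate)))
  invisible(x)
}

#' Tidy a metrics report
#' @param x A [metrics_report()].
#' @param ... Unused.
#' @return One-row-per-metric tibble (`metric`, `value`).
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("aae", "sde", "pearson_r", "bland_mean_diff",
               "bland_loa_low", "bland_loa_high", "roi_success_rate"),
    value = c(x$aae, x$sde, x$pearson_r, x$bland_mean_diff,
              x$bland_loa_low, x$bland_loa_high, x$roi_success_rate))
}

#' Glance at a metrics report
#' @param x A [metrics_report()].
#' @param ... Unused.
#' @return One-row tibble of the headline metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(n = x$n_measurements, aae = x$aae, sde = x$sde,
                 pearson_r = x$pearson_r,
                 bland_mean_diff = x$bland_mean_diff,
                 roi_success_rate = x$roi_success_rate)
}

#' Write a metrics report as JSON
#' @param x A [metrics_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  obj <- x[c("aae", "sde", "n_measurements", "pearson_r", "bland_mean_diff",
             "bland_loa_low", "bland_loa_high", "roi_success_rate")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
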