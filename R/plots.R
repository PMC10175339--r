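# ggplot2 visualisations of results.

#' Plot an RR series
#'
#' Step plot of windowed RR estimates over time, coloured by window quality.
#'
#' @param object An `rr_series` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = (.data$window_start + .data$window_end) / 2,
                               y = .data$rr_bpm, colour = .data$quality)) +
    ggplot2::geom_point() +
    ggplot2::geom_step(ggplot2::aes(group = 1), colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "respiratory rate (bpm)",
                  colour = "quality") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of a metrics report
#'
#' Per-window differences against means with the mean difference and the 95%
#' limits of agreement.
#'
#' @param report A [metrics_report()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  ggplot2::ggplot(report$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = report$bland_mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(report$bland_loa_low, report$bland_loa_high),
                        linetype = "dashed", colour = "indianred") +
    ggplot2::labs(x = "mean RR (bpm)", y = "difference (bpm)") +
    ggplot2::theme_minimal()
}

#' Correlation plot of measured against reference RR
#'
#' @param report A [metrics_report()].
#' @return A ggplot object.
#' @export
plot_correlation <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  ggplot2::ggplot(report$aligned, ggplot2::aes(x = .data$r, y = .data$m)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "reference RR (bpm)", y = "estimated RR (bpm)") +
    ggplot2::theme_minimal()
}

#' Plot a respiratory signal
#'
#' @param object A [resp_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resp_signal <- function(object, ...) {
  ggplot2::ggplot(as_tibble.resp_signal(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "mean ROI intensity") +
    ggplot2::theme_minimal()
}
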