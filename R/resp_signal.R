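# Respiratory-signal extraction and the despike/smooth/bandpass/CZT chain.

#' Per-frame respiratory signal
#'
#' @param values Numeric per-frame series (mean ROI thermal intensity).
#' @param fs Sampling rate (frames per second).
#' @param valid Logical per-frame validity (ROI present); defaults to all TRUE.
#' @param t0 Start time (seconds).
#' @return Object of class `resp_signal`.
#' @export
resp_signal <- function(values, fs, valid = NULL, t0 = 0) {
  values <- as.numeric(values)
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  stopifnot(length(valid) == length(values), fs > 0)
  structure(list(values = values, fs = fs, valid = as.logical(valid), t0 = t0),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal n=%d fs=%g Hz valid=%d/%d t0=%gs>\n",
              length(x$values), x$fs, sum(x$valid), length(x$values), x$t0))
  invisible(x)
}

#' @export
as_tibble.resp_signal <- function(x, ...) {
  tibble::tibble(time = x$t0 + (seq_along(x$values) - 1) / x$fs,
                 value = x$values, valid = x$valid)
}

#' Breathing-band configuration
#'
#' Butterworth passband for the population under study: `[0.1, 0.85]` Hz for
#' healthy adults, `[0.5, 1.5]` Hz for newborn infants.
#'
#' @param population `"adult"` or `"neonate"`, selecting the default band.
#' @param low_hz,high_hz Band edges (Hz); override the population default.
#' @param order Butterworth order of the one-pass filter (applied
#'   forward-backward, so the effective attenuation doubles).
#' @return Object of class `band_config`.
#' @export
band_config <- function(population = c("adult", "neonate"),
                        low_hz = NULL, high_hz = NULL, order = 2L) {
  population <- match.arg(population)
  defaults <- if (population == "adult") c(0.1, 0.85) else c(0.5, 1.5)
  low_hz <- low_hz %||% defaults[1]
  high_hz <- high_hz %||% defaults[2]
  stopifnot(low_hz > 0, high_hz > low_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 population = population),
            class = "band_config")
}

#' Raw respiratory signal from mapped thermal ROIs
#'
#' Per frame, the arithmetic mean of the thermal pixels inside the mapped ROI.
#' Frames without an ROI are marked invalid and gap-filled by linear
#' interpolation between the neighbouring valid samples (edge gaps hold the
#' nearest valid value).
#'
#' @param thermal_frames Function `i -> matrix`, or a list of matrices.
#' @param mapped_rois List (length = frame count) of [roi_box()] in thermal
#'   coordinates, or `NULL`/empty boxes for undetected frames.
#' @param fs Sampling rate (fps).
#' @param t0 Start time (seconds).
#' @return A [resp_signal()].
#' @export
extract_raw_signal <- function(thermal_frames, mapped_rois, fs, t0 = 0) {
  frame_fn <- if (is.function(thermal_frames)) thermal_frames else {
    function(i) thermal_frames[[i]]
  }
  n <- length(mapped_rois)
  vals <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    roi <- mapped_rois[[i]]
    if (is.null(roi) || !inherits(roi, "roi_box") || roi$empty ||
        roi$w < 1 || roi$h < 1) next
    fr <- frame_fn(i)
    rows <- (roi$by + 1):(roi$by + roi$h)
    cols <- (roi$bx + 1):(roi$bx + roi$w)
    vals[i] <- mean(fr[rows, cols])
    valid[i] <- TRUE
  }
  if (!any(valid)) stop("no frame has a valid ROI; cannot extract a signal", call. = FALSE)
  if (!all(valid)) {
    idx <- which(valid)
    vals <- stats::approx(idx, vals[idx], xout = seq_len(n), rule = 2)$y
  }
  resp_signal(vals, fs = fs, valid = valid, t0 = t0)
}

# Classed error for zero-variance signals.
#' @noRd
stop_flat_signal <- function() {
  cond <- structure(class = c("rgbtresp_flat_signal_error", "error", "condition"),
                    list(message = "flat signal: variance is zero", call = NULL))
  stop(cond)
}

#' Normalise a respiratory signal to zero mean and unit standard deviation
#' @param signal A [resp_signal()].
#' @return The normalised [resp_signal()].
#' @export
normalize_signal <- function(signal) {
  stopifnot(inherits(signal, "resp_signal"), length(signal$values) >= 2)
  s <- stats::sd(signal$values)
  if (!is.finite(s) || s <= 0) stop_flat_signal()
  signal$values <- (signal$values - mean(signal$values)) / s
  signal
}

#' Hampel despiking filter
#'
#' Sliding-window outlier rejector: a sample is replaced by the local median
#' when it deviates from it by more than `n_sigma` robust standard deviations
#' (`1.4826 * MAD`). The MAD is floored at `mad_floor` so that spikes in
#' otherwise flat neighbourhoods are still rejected.
#'
#' @param signal A [resp_signal()].
#' @param half_window Window half-width (samples); `NULL` uses one second.
#' @param n_sigma Rejection threshold in robust standard deviations.
#' @param mad_floor Lower bound for the MAD.
#' @return The despiked [resp_signal()].
#' @export
hampel_filter <- function(signal, half_window = NULL, n_sigma = 3,
                          mad_floor = 1e-9) {
  stopifnot(inherits(signal, "resp_signal"))
  if (is.null(half_window)) half_window <- round(signal$fs)
  half_window <- as.integer(half_window)
  stopifnot(half_window >= 1L)
  x <- signal$values
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_window); hi <- min(n, i + half_window)
    w <- x[lo:hi]
    med <- stats::median(w)
    sigma <- 1.4826 * max(stats::median(abs(w - med)), mad_floor)
    if (abs(x[i] - med) > n_sigma * sigma) out[i] <- med
  }
  signal$values <- out
  signal
}

#' Centred moving-average smoother
#'
#' Mean over a centred odd-length window, with partial (shrunken) windows at
#' the record edges.
#'
#' @param signal A [resp_signal()].
#' @param window Window length (odd, >= 1); `NULL` uses `round(fs / 3)`
#'   forced odd.
#' @return The smoothed [resp_signal()].
#' @export
moving_average <- function(signal, window = NULL) {
  stopifnot(inherits(signal, "resp_signal"))
  if (is.null(window)) {
    window <- round(signal$fs / 3)
    if (window %% 2 == 0) window <- window + 1
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L != 1L) {
    stop("moving-average window must be odd and >= 1", call. = FALSE)
  }
  if (window == 1L) return(signal)
  x <- signal$values
  n <- length(x)
  half <- window %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  signal$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  signal
}

#' Zero-phase Butterworth bandpass
#'
#' 2nd-order (by default) Butterworth bandpass with -3 dB points at the band
#' edges, applied forward-backward ([signal::filtfilt()]) so the breathing
#' waveform is not phase-shifted.
#'
#' @param signal A [resp_signal()].
#' @param band A [band_config()].
#' @return The filtered [resp_signal()].
#' @export
bandpass <- function(signal, band) {
  stopifnot(inherits(signal, "resp_signal"), inherits(band, "band_config"))
  nyq <- signal$fs / 2
  if (band$high_hz >= nyq) {
    stop(sprintf("band edge %.3g Hz is at or above Nyquist (%.3g Hz)",
                 band$high_hz, nyq), call. = FALSE)
  }
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq, type = "pass")
  x <- signal$values
  n <- length(x)
  # odd-reflection padding suppresses the start-up transients of the
  # forward-backward pass (the low band edge implies a long impulse response)
  p <- min(n - 1L, ceiling(2 * signal$fs / band$low_hz))
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  signal$values <- yp[(p + 1L):(p + n)]
  signal
}

#' Chirp-Z spectrum on a frequency band
#'
#' Evaluates the discrete-time Fourier transform of `x` on the dense grid
#' `seq(f0, f1, by = df)` using Bluestein's chirp-Z algorithm (FFT
#' convolution), i.e. spectral zooming into the breathing band.
#'
#' @param x Numeric samples.
#' @param fs Sampling rate (Hz).
#' @param f0,f1 Band edges (Hz).
#' @param df Frequency resolution (Hz).
#' @return List with `freq` (Hz) and complex `spectrum`.
#' @export
czt_spectrum <- function(x, fs, f0, f1, df = 0.005) {
  n <- length(x)
  m <- floor((f1 - f0) / df + 1e-9) + 1L
  stopifnot(n >= 2L, m >= 1L)
  freq <- f0 + (0:(m - 1L)) * df
  phi <- pi * df / fs               # half the per-bin phase step
  nn <- 0:(n - 1L)
  kk <- 0:(m - 1L)
  # X_k = sum_n x_n A^{-n} W^{nk}, A = e^{2*pi*i*f0/fs}, W = e^{-2*pi*i*df/fs}
  y <- x * exp(-2i * pi * f0 / fs * nn) * exp(-1i * phi * nn^2)
  jj <- seq(-(n - 1L), m - 1L)
  h <- exp(1i * phi * jj^2)
  L <- stats::nextn(n + m - 1L, 2L)
  conv <- stats::fft(stats::fft(c(y, rep(0, L - n))) *
                       stats::fft(c(h, rep(0, L - length(h)))), inverse = TRUE) / L
  spec <- exp(-1i * phi * kk^2) * conv[n + kk]
  list(freq = freq, spectrum = spec)
}

#' Windowed respiratory-rate estimate by chirp-Z spectral analysis
#'
#' Evaluates the spectrum of the (filtered) window on a dense grid over the
#' breathing band, takes the in-band magnitude peak (ties toward the lower
#' frequency) and converts it to breaths per minute (`rr = 60 * f_peak`). The
#' spectral peak ratio (peak magnitude over median in-band magnitude) is a
#' quality score: near 1 means no dominant breathing component.
#'
#' @param signal A [resp_signal()] (one analysis window, already filtered).
#' @param band A [band_config()].
#' @param freq_resolution Spectral grid step (Hz).
#' @param whiten Optional magnitude response of the conditioning filter,
#'   evaluated on the band grid. When the window passed through a bandpass,
#'   the in-band noise floor is coloured by it, which would bias the
#'   peak/median quality ratio upward; dividing by the response restores a
#'   flat noise floor for the ratio (the peak location itself is unaffected).
#' @return List: `peak_freq_hz`, `rr_bpm`, `spectral_peak_ratio`.
#' @export
estimate_rr_czt <- function(signal, band, freq_resolution = 0.005,
                            whiten = NULL) {
  stopifnot(inherits(signal, "resp_signal"), inherits(band, "band_config"))
  n <- length(signal$values)
  if (n / signal$fs < 2 / band$low_hz) {
    stop(sprintf("window too short: %.3gs < two periods of the %.3g Hz band edge",
                 n / signal$fs, band$low_hz), call. = FALSE)
  }
  sp <- czt_spectrum(signal$values, signal$fs, band$low_hz, band$high_hz,
                     df = freq_resolution)
  mag <- Mod(sp$spectrum)
  pk <- which.max(mag)  # first maximum = lowest frequency on ties
  magq <- mag
  if (!is.null(whiten)) magq <- mag / pmax(whiten, 0.05 * max(whiten))
  ratio <- magq[pk] / stats::median(magq)
  list(peak_freq_hz = sp$freq[pk], rr_bpm = 60 * sp$freq[pk],
       spectral_peak_ratio = ratio)
}

# Magnitude response of the forward-backward Butterworth bandpass on the
# chirp-Z frequency grid (|H|^2: the filter is applied twice).
#' @noRd
bandpass_response <- function(band, fs, freqs) {
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) / (fs / 2),
                       type = "pass")
  z <- exp(-2i * pi * freqs / fs)
  num <- vapply(z, function(zz) sum(bf$b * zz^(seq_along(bf$b) - 1)), 0i)
  den <- vapply(z, function(zz) sum(bf$a * zz^(seq_along(bf$a) - 1)), 0i)
  Mod(num / den)^2
}

#' Sliding-window respiratory-rate series
#'
#' Applies the full conditioning chain to the whole record -- z-score
#' normalisation, Hampel despiking, moving-average smoothing, zero-phase
#' Butterworth bandpass -- then estimates RR by chirp-Z analysis in windows of
#' `window_s` seconds advanced by `step_s` seconds while a full window fits.
#' Windows whose spectral peak ratio falls below `min_peak_ratio` carry
#' `rr_bpm = 0` and quality `"none"`: no detectable breathing component in the
#' band (e.g. a breath pause). Windows overlapping an invalid-ROI gap longer
#' than `max_gap_s` are flagged `"low"`.
#'
#' @param signal A [resp_signal()] (raw, unfiltered).
#' @param band A [band_config()].
#' @param window_s Window length (seconds).
#' @param step_s Sliding step (seconds).
#' @param freq_resolution Chirp-Z grid step (Hz).
#' @param hampel_half_window,hampel_n_sigma,ma_window Chain parameters
#'   (defaults: one second, 3 sigma, `round(fs/3)` forced odd).
#' @param min_peak_ratio Peak-ratio floor below which no rate is declared.
#' @param max_gap_s Invalid-gap length (seconds) above which a window is
#'   flagged low quality.
#' @return An `rr_series` tibble: `window_start`, `window_end`, `rr_bpm`,
#'   `peak_freq_hz`, `spectral_peak_ratio`, `quality`.
#' @export
sliding_rr <- function(signal, band, window_s = 30, step_s = 20,
                       freq_resolution = 0.005, hampel_half_window = NULL,
                       hampel_n_sigma = 3, ma_window = NULL,
                       min_peak_ratio = 4, max_gap_s = 2) {
  stopifnot(inherits(signal, "resp_signal"), inherits(band, "band_config"))
  n <- length(signal$values)
  dur <- n / signal$fs
  if (dur < window_s) {
    stop(sprintf("record (%.3gs) shorter than one %gs window", dur, window_s),
         call. = FALSE)
  }
  filtered <- signal |>
    normalize_signal() |>
    hampel_filter(half_window = hampel_half_window, n_sigma = hampel_n_sigma) |>
    moving_average(window = ma_window) |>
    bandpass(band)

  # invalid-gap run lengths, for quality flagging
  gap_run <- rle(!signal$valid)
  gap_ends <- cumsum(gap_run$lengths)
  gaps <- data.frame(start = (gap_ends - gap_run$lengths)[gap_run$values],
                     len = gap_run$lengths[gap_run$values])

  starts <- seq(0, dur - window_s + 1e-9, by = step_s)
  wlen <- round(window_s * signal$fs)
  m <- floor((band$high_hz - band$low_hz) / freq_resolution + 1e-9) + 1L
  wh <- bandpass_response(band, signal$fs,
                          band$low_hz + (0:(m - 1L)) * freq_resolution)
  rows <- lapply(starts, function(st) {
    i0 <- round(st * signal$fs) + 1L
    idx <- i0:(i0 + wlen - 1L)
    win <- resp_signal(filtered$values[idx], fs = signal$fs,
                       valid = signal$valid[idx], t0 = signal$t0 + st)
    est <- estimate_rr_czt(win, band, freq_resolution = freq_resolution,
                           whiten = wh)
    long_gap <- any(gaps$len / signal$fs > max_gap_s &
                      gaps$start < i0 + wlen & gaps$start + gaps$len > i0)
    quality <- if (est$spectral_peak_ratio < min_peak_ratio) "none"
    else if (long_gap) "low" else "ok"
    tibble::tibble(window_start = signal$t0 + st,
                   window_end = signal$t0 + st + window_s,
                   rr_bpm = if (quality == "none") 0 else est$rr_bpm,
                   peak_freq_hz = if (quality == "none") 0 else est$peak_freq_hz,
                   spectral_peak_ratio = est$spectral_peak_ratio,
                   quality = quality)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rr_series", class(out))
  out
}

#' Write / read an RR series as CSV
#' @param rr An `rr_series` tibble.
#' @param path File path.
#' @return `write_rr_csv` returns `path` invisibly; `read_rr_csv` the tibble.
#' @export
write_rr_csv <- function(rr, path) {
  utils::write.csv(rr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("rr_series", class(out))
  out
}
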