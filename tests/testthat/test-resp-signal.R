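# Signal extraction and the despike/smooth/bandpass/chirp-Z chain.

test_that("raw signal extraction averages the mapped ROI and interpolates gaps", {
  f1 <- matrix(0, 4, 4); f1[1:2, 1:2] <- c(30.0, 29.8, 30.2, 30.0)
  roi <- roi_box(0, 0, 2, 2, coord_frame = "thermal")
  sig <- extract_raw_signal(list(f1), list(roi), fs = 30)
  expect_identical(sig$values, 30.0)
  # constant frames give a constant signal
  frames <- replicate(5, matrix(2.5, 4, 4), simplify = FALSE)
  rois <- replicate(5, roi, simplify = FALSE)
  expect_identical(extract_raw_signal(frames, rois, fs = 30)$values, rep(2.5, 5))
  # an invalid frame between 30.0 and 30.2 interpolates to 30.1, flag retained
  fa <- matrix(30.0, 4, 4); fb <- matrix(30.2, 4, 4)
  sig2 <- extract_raw_signal(list(fa, fb, fb), list(roi, NULL, roi), fs = 30)
  expect_equal(sig2$values[2], 30.1, tolerance = 1e-12)
  expect_identical(sig2$valid, c(TRUE, FALSE, TRUE))
  expect_error(extract_raw_signal(list(fa), list(NULL), fs = 30), "valid ROI")
})

test_that("normalisation gives zero mean and unit sd, is idempotent, and rejects flat signals", {
  s <- normalize_signal(resp_signal(c(1, 2, 3), 1))
  expect_equal(mean(s$values), 0, tolerance = 1e-15)
  expect_equal(sd(s$values), 1, tolerance = 1e-15)
  s2 <- normalize_signal(s)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_error(normalize_signal(resp_signal(rep(4, 10), 1)),
               class = "rgbtresp_flat_signal_error")
})

test_that("the Hampel filter removes spikes, leaves clean signals intact, and matches an independent implementation", {
  s <- hampel_filter(resp_signal(c(1, 1, 1, 100, 1, 1, 1), 1), half_window = 3)
  expect_identical(s$values, rep(1, 7))
  cs <- resp_signal(rep(2, 50), 1)
  expect_identical(hampel_filter(cs, half_window = 5)$values, rep(2, 50))
  # clean sinusoid: at most 1% of samples altered
  x <- sin(2 * pi * 0.8 * (0:899) / 30)
  hf <- hampel_filter(resp_signal(x, 30), half_window = 30, n_sigma = 3)
  expect_lte(mean(hf$values != x), 0.01)
  # cross-check the interior against pracma's Hampel filter
  y <- with_seed_local(8, cumsum(rnorm(200)))
  ours <- hampel_filter(resp_signal(y, 1), half_window = 10, n_sigma = 3)$values
  theirs <- pracma::hampel(y, k = 10, t0 = 3)$y
  expect_equal(ours[11:190], theirs[11:190], tolerance = 1e-12)
})

test_that("the moving average shrinks at edges, is identity at window 1, and reduces white-noise variance", {
  s <- moving_average(resp_signal(c(0, 3, 0), 1), window = 3)
  expect_identical(s$values, c(1.5, 1, 1.5))
  x <- with_seed_local(2, rnorm(500))
  expect_identical(moving_average(resp_signal(x, 1), window = 1)$values, x)
  sm <- moving_average(resp_signal(x, 1), window = 5)
  expect_lt(var(sm$values), var(x))
  expect_error(moving_average(resp_signal(x, 1), window = 4), "odd")
})

test_that("the zero-phase Butterworth bandpass rejects DC, preserves in-band tones, and attenuates out-of-band tones by 20 dB", {
  b <- band_config("adult")
  t <- (0:1799) / 30
  dc <- bandpass(resp_signal(rep(5, 1800) + sin(2 * pi * 0.25 * t), 30), b)
  expect_lte(abs(mean(dc$values)), 5e-3)
  mid <- 301:1500
  a_in <- (max(bandpass(resp_signal(sin(2 * pi * 0.25 * t), 30), b)$values[mid]) -
             min(bandpass(resp_signal(sin(2 * pi * 0.25 * t), 30), b)$values[mid])) / 2
  expect_lt(abs(a_in - 1), 0.1)
  a_out <- (max(bandpass(resp_signal(sin(2 * pi * 5 * t), 30), b)$values[mid]) -
              min(bandpass(resp_signal(sin(2 * pi * 5 * t), 30), b)$values[mid])) / 2
  expect_gte(20 * log10(a_in / a_out), 20)
  expect_error(bandpass(resp_signal(sin(t), 1), b), "Nyquist")
})

test_that("bandpass filtering does not shift the spectral peak of pure tones", {
  b <- band_config("neonate")
  t <- (0:899) / 30
  for (f in c(0.6, 0.8, 1.1)) {
    raw <- resp_signal(sin(2 * pi * f * t), 30)
    filt <- bandpass(raw, b)
    p_raw <- estimate_rr_czt(raw, b)$peak_freq_hz
    p_filt <- estimate_rr_czt(filt, b)$peak_freq_hz
    expect_lte(abs(p_raw - p_filt), 0.005)
  }
})

test_that("the chirp-Z spectrum equals the direct DFT and its peak matches a dense FFT oracle", {
  x <- with_seed_local(4, rnorm(128))
  sp <- czt_spectrum(x, 30, 0.5, 1.5, 0.01)
  nn <- 0:127
  direct <- vapply(sp$freq,
                   function(f) sum(x * exp(-2i * pi * f * nn / 30)), 0i)
  expect_lt(max(Mod(sp$spectrum - direct)), 1e-9)
  # 20 random in-band tones: CZT argmax within one bin of a zero-padded FFT argmax
  b <- band_config("neonate")
  for (seed in 1:20) {
    f_true <- with_seed_local(100 + seed, runif(1, 0.55, 1.45))
    x <- sin(2 * pi * f_true * (0:899) / 30) +
      with_seed_local(200 + seed, rnorm(900, 0, 0.1))
    est <- estimate_rr_czt(resp_signal(x, 30), b)
    # oracle: argmax of a dense zero-padded FFT restricted to the band
    nfft <- 2^17
    X <- Mod(fft(c(x, rep(0, nfft - 900))))
    fgrid <- (0:(nfft - 1)) * 30 / nfft
    inband <- which(fgrid >= 0.5 & fgrid <= 1.5)
    f_fft <- fgrid[inband[which.max(X[inband])]]
    expect_lte(abs(est$peak_freq_hz - f_fft), 0.005 + 30 / nfft)
  }
})

test_that("chirp-Z RR estimation hits known rates and rejects too-short windows", {
  b <- band_config("neonate")
  t <- (0:899) / 30
  est <- estimate_rr_czt(resp_signal(sin(2 * pi * 0.8 * t), 30), b)
  expect_lte(abs(est$rr_bpm - 48), 0.3)
  expect_identical(est$rr_bpm, 60 * est$peak_freq_hz)
  # SNR 10 dB
  x <- sin(2 * pi * 0.8 * t) + with_seed_local(6, rnorm(900, 0, 1 / sqrt(20)))
  est2 <- estimate_rr_czt(resp_signal(x, 30), b)
  expect_lte(abs(est2$rr_bpm - 48), 1)
  expect_error(estimate_rr_czt(resp_signal(sin(t[1:60]), 30), b), "too short")
})

test_that("sliding windows follow the documented arithmetic and recover a constant rate", {
  b <- band_config("neonate")
  t90 <- (0:(90 * 30 - 1)) / 30
  x <- sin(2 * pi * 0.8 * t90) + with_seed_local(7, rnorm(2700, 0, 0.2))
  rr <- sliding_rr(resp_signal(x, 30), b)
  expect_identical(nrow(rr), 4L)
  expect_identical(rr$window_start, c(0, 20, 40, 60))
  expect_identical(rr$window_end, c(30, 50, 70, 90))
  expect_true(all(abs(rr$rr_bpm - 48) <= 1))
  # 80 s record (the stationary acquisition mode lasts 1 min 20 s): 3 windows
  rr80 <- sliding_rr(resp_signal(x[1:2400], 30), b)
  expect_identical(nrow(rr80), 3L)
  expect_error(sliding_rr(resp_signal(x[1:600], 30), b), "shorter")
  # determinism: identical input gives bit-identical output
  rr2 <- sliding_rr(resp_signal(x, 30), b)
  expect_identical(rr$rr_bpm, rr2$rr_bpm)
})

test_that("RR series round-trip through CSV", {
  b <- band_config("neonate")
  x <- sin(2 * pi * 0.8 * (0:2699) / 30) + with_seed_local(7, rnorm(2700, 0, 0.2))
  rr <- sliding_rr(resp_signal(x, 30), b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rr, path)
  rr2 <- read_rr_csv(path)
  expect_equal(rr2$rr_bpm, rr$rr_bpm, tolerance = 1e-9)
  expect_s3_class(rr2, "rr_series")
})
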