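#' Log-Gabor filter bank parameters
#'
#' Settings for the quadrature log-Gabor bank used by the phase-congruency
#' feature stage. A log-Gabor filter has a Gaussian transfer function on a
#' logarithmic frequency axis and exactly zero response at DC, which makes the
#' derived phase-congruency maps invariant to additive intensity offsets.
#'
#' @param n_scales Number of filter scales (>= 2). Scale `k` is centred on
#'   wavelength `min_wavelength * scale_mult^(k-1)` pixels.
#' @param n_orientations Number of orientation channels (>= 3), uniformly
#'   spaced over `[0, pi)`.
#' @param min_wavelength Wavelength (pixels) of the finest-scale filter.
#' @param scale_mult Multiplicative wavelength step between successive scales.
#' @param sigma_on_f Radial bandwidth parameter: ratio of the Gaussian sigma to
#'   the centre frequency on the log axis (0.55 gives roughly 2 octaves).
#' @param angular_spread Sigma (radians) of the angular Gaussian. `NULL`
#'   (default) uses `(pi / n_orientations) / 1.2`.
#' @param noise_k Number of noise-amplitude standard deviations above the
#'   estimated noise mean used for the soft threshold `T_N`.
#' @param epsilon Small positive constant guarding divisions.
#' @param weight_gain,weight_cutoff Gain and cutoff of the sigmoidal
#'   frequency-spread weight that penalises narrowband (single-scale) responses.
#' @return An object of class `log_gabor_params`.
#' @export
log_gabor_params <- function(n_scales = 4L, n_orientations = 6L,
                             min_wavelength = 3, scale_mult = 2.1,
                             sigma_on_f = 0.55, angular_spread = NULL,
                             noise_k = 2.0, epsilon = 1e-4,
                             weight_gain = 10, weight_cutoff = 0.5) {
  stopifnot(n_scales >= 2, n_orientations >= 3, min_wavelength >= 2,
            scale_mult > 1, sigma_on_f > 0, sigma_on_f < 1,
            noise_k >= 0, epsilon > 0)
  if (is.null(angular_spread)) angular_spread <- (pi / n_orientations) / 1.2
  stopifnot(angular_spread > 0)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 min_wavelength = min_wavelength, scale_mult = scale_mult,
                 sigma_on_f = sigma_on_f, angular_spread = angular_spread,
                 noise_k = noise_k, epsilon = epsilon,
                 weight_gain = weight_gain, weight_cutoff = weight_cutoff),
            class = "log_gabor_params")
}

#' Build a frequency-domain log-Gabor filter bank
#'
#' Constructs `n_scales * n_orientations` one-sided (analytic) transfer
#' functions on the FFT grid of the mirror-padded image. Each filter is the
#' product of a radial log-Gabor and an angular Gaussian; because the angular
#' component selects a single half-plane, the inverse FFT of a filtered image
#' is complex, with the real part the even (line) response and the imaginary
#' part the odd (edge) response of the quadrature pair.
#'
#' @param shape Image dimensions `c(nrow, ncol)`; both must be >= 16.
#' @param params A [log_gabor_params()] object.
#' @param pad Mirror-padding width (pixels) applied before FFT filtering to
#'   suppress wrap-around edge artefacts.
#' @return An object of class `log_gabor_bank`: list of transfer-function
#'   matrices `filters[[k]][[o]]` on the padded grid, the radial components
#'   `radial[[k]]`, and the padding geometry used by [filter_responses()].
#' @export
build_log_gabor_bank <- function(shape, params = log_gabor_params(), pad = 16L) {
  stopifnot(inherits(params, "log_gabor_params"), length(shape) == 2)
  if (shape[1] < 16 || shape[2] < 16) {
    stop(sprintf("image too small for log-Gabor analysis: %dx%d (need >= 16x16)",
                 shape[1], shape[2]), call. = FALSE)
  }
  nr0 <- as.integer(shape[1]); nc0 <- as.integer(shape[2])
  nr <- stats::nextn(nr0 + 2L * pad, c(2L, 3L, 5L))
  nc <- stats::nextn(nc0 + 2L * pad, c(2L, 3L, 5L))
  pad_top <- (nr - nr0) %/% 2L; pad_left <- (nc - nc0) %/% 2L

  # FFT-ordered frequency grids (cycles/pixel)
  fy <- (((0:(nr - 1)) + nr %/% 2L) %% nr - nr %/% 2L) / nr
  fx <- (((0:(nc - 1)) + nc %/% 2L) %% nc - nc %/% 2L) / nc
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  radius <- sqrt(FX^2 + FY^2)
  radius[1, 1] <- 1  # avoid log(0); DC is zeroed explicitly below
  theta <- atan2(-FY, FX)

  # gentle low-pass to kill the highest corner frequencies (reduces ringing)
  lowpass <- 1 / (1 + (radius / 0.45)^30)

  log_sd2 <- 2 * log(params$sigma_on_f)^2
  radial <- vector("list", params$n_scales)
  for (k in seq_len(params$n_scales)) {
    wavelength <- params$min_wavelength * params$scale_mult^(k - 1)
    f0 <- 1 / wavelength
    g <- exp(-(log(radius / f0))^2 / log_sd2) * lowpass
    g[1, 1] <- 0
    radial[[k]] <- g
  }

  st <- sin(theta); ct <- cos(theta)
  spreads <- vector("list", params$n_orientations)
  for (o in seq_len(params$n_orientations)) {
    ang <- (o - 1) * pi / params$n_orientations
    ds <- st * cos(ang) - ct * sin(ang)
    dc <- ct * cos(ang) + st * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spreads[[o]] <- exp(-dtheta^2 / (2 * params$angular_spread^2))
  }

  filters <- vector("list", params$n_scales)
  for (k in seq_len(params$n_scales)) {
    filters[[k]] <- lapply(spreads, function(s) radial[[k]] * s)
  }

  structure(list(filters = filters, radial = radial, params = params,
                 shape = c(nr0, nc0), padded_shape = c(nr, nc),
                 pad_top = pad_top, pad_left = pad_left),
            class = "log_gabor_bank")
}

#' Quadrature filter responses of an image
#'
#' Applies every filter of a log-Gabor bank in the frequency domain (after
#' mirror padding) and returns the even/odd quadrature responses together with
#' the amplitude `sqrt(even^2 + odd^2)`.
#'
#' @param image Numeric matrix, all values finite.
#' @param bank A [build_log_gabor_bank()] object built for `dim(image)`.
#' @return Object of class `filter_responses`: arrays `even`, `odd`,
#'   `amplitude`, each `nrow x ncol x n_scales x n_orientations`.
#' @export
filter_responses <- function(image, bank) {
  stopifnot(inherits(bank, "log_gabor_bank"))
  assert_image(image)
  assert_finite_image(image)
  if (!all(dim(image) == bank$shape)) {
    stop("image dimensions do not match the bank shape", call. = FALSE)
  }
  p <- bank$params
  nr0 <- bank$shape[1]; nc0 <- bank$shape[2]
  nr <- bank$padded_shape[1]; nc <- bank$padded_shape[2]
  padded <- pad_mirror(image, bank$pad_top, nr - nr0 - bank$pad_top,
                       bank$pad_left, nc - nc0 - bank$pad_left)
  IM <- fft2(padded)
  rows <- bank$pad_top + seq_len(nr0)
  cols <- bank$pad_left + seq_len(nc0)

  even <- array(0, c(nr0, nc0, p$n_scales, p$n_orientations))
  odd <- array(0, c(nr0, nc0, p$n_scales, p$n_orientations))
  for (k in seq_len(p$n_scales)) {
    for (o in seq_len(p$n_orientations)) {
      resp <- ifft2(IM * bank$filters[[k]][[o]])[rows, cols]
      even[, , k, o] <- Re(resp)
      odd[, , k, o] <- Im(resp)
    }
  }
  structure(list(even = even, odd = odd, amplitude = sqrt(even^2 + odd^2),
                 params = p, shape = c(nr0, nc0)),
            class = "filter_responses")
}

#' Per-orientation phase congruency maps
#'
#' Phase congruency marks pixels where the quadrature responses across scales
#' agree in phase, a contrast-invariant signature of edges and corners. For
#' each orientation the scale responses are projected onto the unit mean-phase
#' vector, a Rayleigh-model noise threshold is soft-subtracted from the total
#' energy, a sigmoidal frequency-spread weight penalises narrowband responses,
#' and the result is normalised by the total amplitude.
#'
#' @param responses A [filter_responses()] object.
#' @param params The [log_gabor_params()] used to build the bank (defaults to
#'   the parameters carried by `responses`).
#' @return Object of class `pc_maps`: array `pc` (`nr x nc x n_orientations`,
#'   values in \[0, 1\]), `weights`, `energy`, `total_amplitude`,
#'   `mean_phase_even`, `mean_phase_odd`, vector `noise_thresholds`, and the
#'   orientation angles (radians).
#' @export
phase_congruency <- function(responses, params = responses$params) {
  stopifnot(inherits(responses, "filter_responses"))
  p <- params
  nr <- responses$shape[1]; nc <- responses$shape[2]
  no <- p$n_orientations; ns <- p$n_scales
  eps <- p$epsilon

  pc <- array(0, c(nr, nc, no))
  weights <- array(0, c(nr, nc, no))
  energy <- array(0, c(nr, nc, no))
  ar <- array(0, c(nr, nc, no))
  mpe <- array(0, c(nr, nc, no))
  mpo <- array(0, c(nr, nc, no))
  tn <- numeric(no)

  for (o in seq_len(no)) {
    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAmp <- matrix(0, nr, nc); maxAmp <- matrix(0, nr, nc)
    for (k in seq_len(ns)) {
      sumE <- sumE + responses$even[, , k, o]
      sumO <- sumO + responses$odd[, , k, o]
      a <- responses$amplitude[, , k, o]
      sumAmp <- sumAmp + a
      maxAmp <- pmax(maxAmp, a)
    }
    ARo <- sqrt(sumE^2 + sumO^2) + eps
    me <- sumE / ARo; mo <- sumO / ARo

    Etot <- matrix(0, nr, nc)
    for (k in seq_len(ns)) {
      ek <- responses$even[, , k, o]; ok <- responses$odd[, , k, o]
      Etot <- Etot + ek * me + ok * mo - abs(ek * mo - ok * me)
    }

    # Rayleigh noise model from the finest-scale amplitude (median-based)
    tau <- stats::median(responses$amplitude[, , 1, o]) / sqrt(log(4))
    mult_sum <- (1 - (1 / p$scale_mult)^ns) / (1 - 1 / p$scale_mult)
    total_tau <- tau * mult_sum
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sd <- total_tau * sqrt((4 - pi) / 2)
    Tn <- noise_mean + p$noise_k * noise_sd

    width <- (sumAmp / (maxAmp + eps)) / ns
    w <- 1 / (1 + exp(p$weight_gain * (p$weight_cutoff - width)))

    pc[, , o] <- w * pmax(Etot - Tn, 0) / (sumAmp + eps)
    weights[, , o] <- w
    energy[, , o] <- Etot
    ar[, , o] <- ARo
    mpe[, , o] <- me
    mpo[, , o] <- mo
    tn[o] <- Tn
  }

  structure(list(pc = pc, weights = weights, energy = energy,
                 total_amplitude = ar, mean_phase_even = mpe,
                 mean_phase_odd = mpo, noise_thresholds = tn,
                 orientation_angles = (seq_len(no) - 1) * pi / no,
                 shape = c(nr, nc), params = p),
            class = "pc_maps")
}

#' Maximum/minimum moment maps of per-orientation phase congruency
#'
#' Treats the per-orientation phase-congruency values at each pixel as an
#' angular distribution and computes its principal second moments. The maximum
#' moment `M` is large on both edges and corners; the minimum moment `m` is
#' large only where congruency is strong in several orientations (corners).
#'
#' @param pc A [phase_congruency()] result.
#' @return Object of class `moment_maps` with matrices `p`, `q`, `r`
#'   (accumulators), `M`, `m`, and the orientation angles.
#' @export
moment_maps <- function(pc) {
  stopifnot(inherits(pc, "pc_maps"))
  nr <- pc$shape[1]; nc <- pc$shape[2]
  pm <- matrix(0, nr, nc); qm <- matrix(0, nr, nc); rm_ <- matrix(0, nr, nc)
  for (o in seq_along(pc$orientation_angles)) {
    phi <- pc$orientation_angles[o]
    cpc <- pc$pc[, , o] * cos(phi)
    spc <- pc$pc[, , o] * sin(phi)
    pm <- pm + cpc^2
    qm <- qm + 2 * cpc * spc
    rm_ <- rm_ + spc^2
  }
  disc <- sqrt(qm^2 + (pm - rm_)^2)
  structure(list(p = pm, q = qm, r = rm_,
                 M = 0.5 * (rm_ + pm + disc), m = 0.5 * (rm_ + pm - disc),
                 orientation_angles = pc$orientation_angles, shape = c(nr, nc)),
            class = "moment_maps")
}

#' Dominant-orientation index map
#'
#' For each pixel, sums the filter amplitude over scales within each
#' orientation channel and records the 1-based index of the channel with the
#' largest summed amplitude (ties broken toward the lowest index). The index
#' map is invariant under positive rescaling of the image and is the basis of
#' the keypoint descriptors.
#'
#' @param responses A [filter_responses()] object.
#' @return Object of class `orientation_index_map`: integer matrix `index` in
#'   `[1, n_orientations]` and matrix `max_amplitude`.
#' @export
orientation_index_map <- function(responses) {
  stopifnot(inherits(responses, "filter_responses"))
  nr <- responses$shape[1]; nc <- responses$shape[2]
  no <- responses$params$n_orientations
  stacked <- matrix(0, nr * nc, no)
  for (o in seq_len(no)) {
    s <- matrix(0, nr, nc)
    for (k in seq_len(responses$params$n_scales)) {
      s <- s + responses$amplitude[, , k, o]
    }
    stacked[, o] <- as.vector(s)
  }
  idx <- max.col(stacked, ties.method = "first")
  mx <- stacked[cbind(seq_len(nr * nc), idx)]
  structure(list(index = matrix(idx, nr, nc),
                 max_amplitude = matrix(mx, nr, nc),
                 n_orientations = no, shape = c(nr, nc)),
            class = "orientation_index_map")
}
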