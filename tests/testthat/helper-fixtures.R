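# Shared fixtures, built in code.

# Phase-congruency chain on a small image with default parameters.
pc_chain <- function(img, params = log_gabor_params()) {
  bank <- build_log_gabor_bank(dim(img), params)
  resp <- filter_responses(img, bank)
  pc <- phase_congruency(resp)
  list(bank = bank, resp = resp, pc = pc, mom = moment_maps(pc),
       oim = orientation_index_map(resp))
}

# 64x64 bright square on dark ground; corners at (22,22),(41,22),(22,41),(41,41).
square_image <- function() {
  img <- matrix(0, 64, 64)
  img[23:42, 23:42] <- 1
  img
}

# Horizontal-frequency tone (intensity varies along x), wavelength in px.
tone_image <- function(n = 64, wavelength = 8) {
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  sin(2 * pi * xs / wavelength)
}

# Minimal hand-built pc_maps with constant per-orientation PC values.
fake_pc_maps <- function(values, shape = c(8, 8)) {
  no <- length(values)
  pc <- array(0, c(shape, no))
  for (o in seq_len(no)) pc[, , o] <- values[o]
  structure(list(pc = pc, orientation_angles = (seq_len(no) - 1) * pi / no,
                 shape = shape),
            class = "pc_maps")
}

# A match_set over explicit index pairs.
manual_matches <- function(n) {
  structure(list(pairs = tibble::tibble(index_a = seq_len(n),
                                        index_b = seq_len(n),
                                        ssd_distance = 0),
                 nndr_threshold = 1),
            class = "match_set")
}

# Scripted landmark detector: succeeds with fixed landmarks except on frames
# listed in `fail_frames` (tracks its own call count).
scripted_detector <- function(lm, fail_frames = integer()) {
  count <- 0L
  function(frame) {
    count <<- count + 1L
    if (count %in% fail_frames) return(list(landmarks = NULL, confidence = 0))
    list(landmarks = lm, confidence = 1)
  }
}

# Visible-style frame with a textured face patch and coded fiducial markers
# placed per `lm`; `blank = TRUE` suppresses markers and texture.
fiducial_frame <- function(lm, shape = c(240, 320), blank = FALSE, seed = 1) {
  fr <- with_seed_local(seed, matrix(stats::runif(prod(shape), 0.3, 0.5),
                                     shape[1], shape[2]))
  if (blank) return(fr)
  levels <- fiducial_levels()
  off <- cbind(c(0, 1, -1, 0, 0, 2, -2, 0, 0), c(0, 0, 0, 1, -1, 0, 0, 2, -2))
  for (nm in names(levels)) {
    p <- lm[[nm]]
    mx <- round(p[1]) + off[, 1]; my <- round(p[2]) + off[, 2]
    ok <- mx >= 0 & my >= 0 & mx < shape[2] & my < shape[1]
    fr[cbind(my[ok] + 1, mx[ok] + 1)] <- levels[[nm]]
  }
  fr
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Mean corner reprojection error (thermal px) between two visible->thermal maps
# over the visible frame corners.
corner_error <- function(map, truth, rgb_shape = c(720, 960)) {
  corners <- rbind(c(0, 0), c(rgb_shape[2] - 1, 0), c(0, rgb_shape[1] - 1),
                   c(rgb_shape[2] - 1, rgb_shape[1] - 1))
  mean(sqrt(rowSums((apply_affine(map, corners) - apply_affine(truth, corners))^2)))
}
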