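# Log-Gabor bank, phase congruency, moment maps, orientation index map.

test_that("log-Gabor filters have zero DC gain, uniform orientations, and radial peaks at the design wavelengths", {
  params <- log_gabor_params(n_orientations = 6L)
  bank <- build_log_gabor_bank(c(64, 64), params)
  for (k in seq_len(params$n_scales)) {
    for (o in seq_len(params$n_orientations)) {
      expect_identical(bank$filters[[k]][[o]][1, 1], 0)
    }
  }
  # radial gain peaks at the design wavelength, within one frequency bin
  nc <- bank$padded_shape[2]
  for (k in seq_len(params$n_scales)) {
    wl <- params$min_wavelength * params$scale_mult^(k - 1)
    peak_bin <- which.max(bank$radial[[k]][1, 1:(nc %/% 2)]) - 1
    expect_lte(abs(peak_bin - nc / wl), 1)
  }
  # orientation lobes are spaced pi/6 apart: the angular response maximum of
  # channel o along a fixed-radius circle sits at (o-1)*pi/6
  nr <- bank$padded_shape[1]
  angs <- seq(0, pi - 1e-6, length.out = 180)
  rad_bin <- 12
  for (o in 1:6) {
    g <- vapply(angs, function(a) {
      fx <- rad_bin * cos(a) / nc
      fy <- -rad_bin * sin(a) / nr
      ix <- (round(fx * nc) + nc) %% nc + 1
      iy <- (round(fy * nr) + nr) %% nr + 1
      bank$filters[[2]][[o]][iy, ix]
    }, 0)
    expect_lt(abs(angs[which.max(g)] - (o - 1) * pi / 6), pi / 36)
  }
  expect_error(build_log_gabor_bank(c(8, 8)), "too small")
})

test_that("quadrature responses vanish on constant images and satisfy the amplitude identity", {
  ch <- pc_chain(matrix(7.3, 64, 64))
  expect_lt(max(abs(ch$resp$even)), 1e-9)
  expect_lt(max(abs(ch$resp$odd)), 1e-9)
  expect_lt(max(ch$resp$amplitude), 1e-9)
  for (seed in 1:3) {
    img <- with_seed_local(seed, matrix(rnorm(64 * 64), 64, 64))
    r <- pc_chain(img)$resp
    expect_lt(max(abs(r$amplitude - sqrt(r$even^2 + r$odd^2))), 1e-12)
  }
})

test_that("non-finite pixels are rejected with their location", {
  bank <- build_log_gabor_bank(c(64, 64))
  img <- matrix(0, 64, 64)
  img[11, 21] <- NA  # (x=20, y=10) 0-based
  expect_error(filter_responses(img, bank), "x=20, y=10")
})

test_that("a pure tone concentrates amplitude in the aligned orientation channel, matching the transfer-function prediction", {
  params <- log_gabor_params()
  img <- tone_image(64, wavelength = 8)
  ch <- pc_chain(img, params)
  measured <- vapply(1:6, function(o) {
    mean(vapply(1:4, function(k) mean(ch$resp$amplitude[17:48, 17:48, k, o]), 0))
  }, 0)
  # oracle: evaluate the bank transfer functions at the tone's +f and -f bins
  # (a real sinusoid has both spectral components; the one-sided filters of
  # opposite-leaning channels pick up the negative-frequency lobe)
  nc <- ch$bank$padded_shape[2]
  bin <- round(nc / 8) + 1
  nbin <- nc - (bin - 1) + 1
  predicted <- vapply(1:6, function(o) {
    mean(vapply(1:4, function(k) {
      ch$bank$filters[[k]][[o]][1, bin] + ch$bank$filters[[k]][[o]][1, nbin]
    }, 0))
  }, 0)
  expect_identical(which.max(measured), which.max(predicted))
  expect_identical(which.max(measured), 1L)
  m_rel <- measured / max(measured)
  p_rel <- predicted / max(predicted)
  expect_lt(max(abs(m_rel - p_rel)), 0.15)
})

test_that("phase congruency is near zero on constant images, bounded, and peaks on step edges", {
  ch <- pc_chain(matrix(4, 64, 64))
  expect_lte(max(ch$pc$pc), 1e-6)

  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  pcs <- pc_chain(step)$pc$pc
  pcmax <- apply(pcs, c(1, 2), max)
  edge_mean <- mean(pcmax[, 32:33])
  far_mean <- mean(pcmax[, c(1:27, 38:64)])
  expect_gte(edge_mean, 3 * far_mean)

  for (seed in 1:3) {
    img <- with_seed_local(seed, matrix(runif(64 * 64), 64, 64))
    p <- pc_chain(img)$pc$pc
    expect_gte(min(p), 0)
    expect_lte(max(p), 1 + 1e-6)
  }
})

test_that("phase congruency and the orientation index map are invariant to affine intensity changes", {
  img <- square_image() + tone_image(64, 12) * 0.2
  a <- pc_chain(img)
  b <- pc_chain(0.5 * img + 20)
  expect_lte(mean(abs(a$pc$pc - b$pc$pc)), 0.05)
  expect_identical(a$oim$index, pc_chain(2 * img)$oim$index)
})

test_that("moment maps satisfy the hand-evaluated cases and the trace identities", {
  # single orientation phi = 0 with constant PC = c
  c0 <- 0.6
  m1 <- moment_maps(fake_pc_maps(c0))
  expect_equal(max(abs(m1$p - c0^2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(m1$q)), 0, tolerance = 1e-12)
  expect_equal(max(abs(m1$r)), 0, tolerance = 1e-12)
  expect_equal(max(abs(m1$M - c0^2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(m1$m)), 0, tolerance = 1e-12)
  # two orthogonal orientations with equal PC: isotropic, M = m = c^2
  m2 <- moment_maps(fake_pc_maps(c(c0, c0), shape = c(4, 4)))
  expect_lt(max(abs(m2$M - c0^2)), 1e-12)
  expect_lt(max(abs(m2$m - c0^2)), 1e-12)
  # all-zero PC
  m0 <- moment_maps(fake_pc_maps(c(0, 0, 0)))
  expect_identical(max(abs(c(m0$p, m0$q, m0$r, m0$M, m0$m))), 0)
  # identities on random PC stacks
  for (seed in 1:5) {
    pcv <- with_seed_local(seed, array(runif(8 * 8 * 6), c(8, 8, 6)))
    pm <- structure(list(pc = pcv, orientation_angles = (0:5) * pi / 6,
                         shape = c(8, 8)), class = "pc_maps")
    mm <- moment_maps(pm)
    expect_lt(max(abs(mm$M + mm$m - (mm$p + mm$r))), 1e-9)
    expect_lt(max(abs((mm$M - mm$m) - sqrt(mm$q^2 + (mm$p - mm$r)^2))), 1e-9)
    expect_gte(min(mm$M - mm$m), -1e-12)
  }
})

test_that("the orientation index map picks the aligned channel, is scale invariant, and breaks ties toward the lowest index", {
  ch <- pc_chain(tone_image(64, 8))
  interior <- ch$oim$index[11:54, 11:54]
  expect_gte(mean(interior == 1L), 0.9)
  # ties: equal summed amplitude in all channels -> index 1
  fake <- structure(list(amplitude = array(1, c(4, 4, 2, 3)),
                         params = list(n_scales = 2L, n_orientations = 3L),
                         shape = c(4, 4)),
                    class = "filter_responses")
  expect_true(all(orientation_index_map(fake)$index == 1L))
})
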