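# Keypoints, descriptors, matching, FSC, rig scale adjustment, full registration.

test_that("FAST keypoint detection finds the corners of a bright square and respects max_points", {
  ch <- pc_chain(square_image())
  kps <- detect_keypoints(ch$mom, max_points = 50L)
  truth <- rbind(c(22, 22), c(41, 22), c(22, 41), c(41, 41))
  for (i in 1:4) {
    d <- sqrt((kps$x - truth[i, 1])^2 + (kps$y - truth[i, 2])^2)
    expect_lte(min(d), 2)
  }
  expect_true(all(kps$source %in% c("maximum", "minimum")))
  expect_lte(nrow(detect_keypoints(ch$mom, max_points = 3L)), 3L)
  # all-zero maps: no corners
  zero <- structure(list(M = matrix(0, 32, 32), m = matrix(0, 32, 32),
                         shape = c(32, 32)), class = "moment_maps")
  expect_identical(nrow(detect_keypoints(zero)), 0L)
})

test_that("orientation-index descriptors are deterministic, scale invariant, and of the documented length", {
  img <- square_image() + 0.3 * tone_image(64, 10)
  ch <- pc_chain(img)
  kps <- detect_keypoints(ch$mom, max_points = 10L)
  d1 <- describe_keypoints(ch$oim, kps, patch_size = 24L, grid = 4L)
  expect_gt(nrow(d1$descriptors), 0L)
  expect_identical(ncol(d1$descriptors), 4L * 4L * 6L)
  expect_equal(sqrt(rowSums(d1$descriptors^2)), rep(1, nrow(d1$descriptors)))
  # positive rescaling leaves the index map, hence the descriptors, unchanged
  ch2 <- pc_chain(2 * img)
  d2 <- describe_keypoints(ch2$oim, kps, patch_size = 24L, grid = 4L)
  expect_equal(d1$descriptors, d2$descriptors, tolerance = 1e-12)
  # keypoints whose patch exits the image are dropped
  edge_kp <- tibble::tibble(x = 2L, y = 2L, source = "maximum", score = 1)
  expect_identical(nrow(describe_keypoints(ch$oim, edge_kp, 24L, 4L)$keypoints), 0L)
  expect_error(describe_keypoints(ch$oim, kps, patch_size = 25L, grid = 4L),
               "multiple")
})

test_that("SSD/NNDR matching self-matches, honours the ratio boundary, and recovers planted correspondences", {
  set.seed(3)
  a <- matrix(runif(20 * 16), 20, 16)
  a <- a / sqrt(rowSums(a^2))
  ms <- match_descriptors(a, a, nndr = 1.0)
  expect_identical(nrow(ms$pairs), 20L)
  expect_identical(ms$pairs$index_a, ms$pairs$index_b)
  expect_lt(max(ms$pairs$ssd_distance), 1e-12)
  # planted pairs with decoys
  true_a <- matrix(runif(30 * 16), 30, 16); true_a <- true_a / sqrt(rowSums(true_a^2))
  b <- true_a + matrix(rnorm(30 * 16, 0, 0.02), 30, 16)
  b <- b / sqrt(rowSums(b^2))
  decoys <- matrix(runif(10 * 16), 10, 16); decoys <- decoys / sqrt(rowSums(decoys^2))
  ms2 <- match_descriptors(true_a, rbind(b, decoys), nndr = 0.8)
  correct <- sum(ms2$pairs$index_b == ms2$pairs$index_a)
  expect_gte(correct, 25L)
  # one-to-one on each side
  expect_false(any(duplicated(ms2$pairs$index_a)))
  expect_false(any(duplicated(ms2$pairs$index_b)))
  # fewer than 2 candidates: empty result
  expect_identical(nrow(match_descriptors(a[1, , drop = FALSE], a)$pairs), 0L)
})

test_that("fast sample consensus recovers exact, contaminated, and identity transforms deterministically", {
  set.seed(42)
  pa <- cbind(runif(50, 0, 200), runif(50, 0, 200))
  truth <- affine_similarity(3, 4 * pi / 180, 12, -7)
  pb <- apply_affine(truth, pa)
  ka <- tibble::tibble(x = pa[, 1], y = pa[, 2])
  kb <- tibble::tibble(x = pb[, 1], y = pb[, 2])
  ms <- manual_matches(50)
  est <- estimate_affine_fsc(ms, ka, kb, seed = 7)
  expect_lt(max(abs(est$matrix - truth$matrix)), 1e-6)
  expect_identical(est$inlier_count, 50L)
  # 20% gross outliers
  pb2 <- pb
  pb2[1:10, ] <- cbind(runif(10, 0, 300), runif(10, 0, 300))
  kb2 <- tibble::tibble(x = pb2[, 1], y = pb2[, 2])
  est2 <- estimate_affine_fsc(ms, ka, kb2, seed = 7)
  corners <- rbind(c(0, 0), c(200, 0), c(0, 200), c(200, 200))
  err <- sqrt(rowSums((apply_affine(est2, corners) - apply_affine(truth, corners))^2))
  expect_lte(max(err), 0.5)
  # determinism under a fixed seed
  est3 <- estimate_affine_fsc(ms, ka, kb2, seed = 7)
  expect_identical(est2$matrix, est3$matrix)
  # identity correspondences
  esti <- estimate_affine_fsc(ms, ka, ka, seed = 1)
  expect_lt(max(abs(esti$matrix - cbind(diag(2), c(0, 0)))), 1e-9)
  expect_lt(esti$rms_residual, 1e-9)
  # failure contracts
  expect_error(estimate_affine_fsc(manual_matches(2), ka, kb, seed = 1),
               class = "rgbtresp_registration_error")
})

test_that("rig scale adjustment recovers a scale-3 similarity within 1% and half a thermal pixel", {
  truth <- affine_similarity(1 / 3, 0, 10, 5)
  rp <- generate_rig_pair(truth, seed = 3)
  rig <- scale_adjust_from_rig(rp$rgb, rp$thermal, c(6, 5))
  expect_identical(rig$provenance, "rig")
  expect_lt(abs(1 / rig$matrix[1, 1] - 3), 0.01 * 3)
  pred <- apply_affine(rig, rp$corners_rgb)
  expect_lt(max(sqrt(rowSums((pred - apply_affine(truth, rp$corners_rgb))^2))), 0.5)
  # identical frames: identity similarity
  same <- generate_rig_pair(affine_identity(), rgb_shape = c(240L, 320L),
                            thermal_shape = c(240L, 320L), square_px = 24,
                            seed = 4)
  rig2 <- scale_adjust_from_rig(same$rgb, same$rgb, c(6, 5))
  expect_lt(abs(rig2$matrix[1, 1] - 1), 1e-3)
  expect_lt(max(abs(rig2$matrix[, 3])), 0.1)
  # rig absent: error naming the modality
  flat <- matrix(0.5, 240, 320)
  err <- tryCatch(scale_adjust_from_rig(flat, same$rgb, c(6, 5)),
                  error = function(e) e)
  expect_s3_class(err, "rgbtresp_registration_error")
  expect_match(conditionMessage(err), "visible")
})

test_that("the full two-phase registration recovers synthetic similarity+affine misalignments", {
  truth <- affine_similarity(1 / 2.8, 3 * pi / 180, 4, -3)
  sp <- generate_structured_pair(truth, seed = 5)
  rp <- generate_rig_pair(truth, seed = 5)
  rig <- scale_adjust_from_rig(rp$rgb, rp$thermal, c(6, 5))
  m <- register_rgbt(sp$rgb, sp$thermal, rig_map = rig)
  expect_identical(m$provenance, "composed")
  expect_lte(corner_error(m, truth), 2)
  # self-registration: composed map within 0.5 px of identity on the corners
  frame <- sp$thermal
  m2 <- register_rgbt(frame, frame, rig_map = affine_identity())
  expect_lte(corner_error(m2, affine_identity(), rgb_shape = dim(frame)), 0.5)
  # featureless pair fails at the keypoint stage
  err <- tryCatch(register_rgbt(matrix(1, 64, 64), matrix(1, 64, 64)),
                  error = function(e) e)
  expect_s3_class(err, "rgbtresp_registration_error")
  expect_identical(err$stage, "keypoints")
})

test_that("ROI mapping rounds outward, clips, flags empty boxes, and contains the original under round-trips", {
  thermal_shape <- c(240, 320)
  box <- roi_box(90, 94, 20, 18)
  ident <- map_roi(box, affine_identity(), thermal_shape)
  expect_identical(c(ident$bx, ident$by, ident$w, ident$h), c(90, 94, 20, 18))
  third <- map_roi(box, affine_similarity(1 / 3, 0, 0, 0), thermal_shape)
  expect_identical(c(third$bx, third$by, third$w, third$h), c(30, 31, 7, 7))
  outside <- map_roi(roi_box(0, 0, 10, 10),
                     affine_similarity(1, 0, 1000, 1000), thermal_shape)
  expect_true(outside$empty)
  # outward-rounding monotonicity: forward then inverse mapping contains the box
  m <- affine_similarity(1 / 2.5, 2 * pi / 180, 8, -4)
  fwd <- map_roi(box, m, thermal_shape)
  back <- map_roi(fwd, invert_affine(m), c(720, 960))
  expect_lte(back$bx, box$bx); expect_lte(back$by, box$by)
  expect_gte(back$bx + back$w, box$bx + box$w)
  expect_gte(back$by + back$h, box$by + box$h)
})

test_that("affine maps validate, invert, compose, and round-trip through JSON", {
  expect_error(affine_map(rbind(c(1, 2, 0), c(2, 4, 0))), "singular")
  m <- affine_similarity(1 / 3, 2 * pi / 180, 5, -2)
  pts <- cbind(runif(10, 0, 900), runif(10, 0, 700))
  rt <- apply_affine(invert_affine(m), apply_affine(m, pts))
  expect_lt(max(abs(rt - pts)), 1e-6)
  comp <- compose_affine(invert_affine(m), m)
  expect_lt(max(abs(comp$matrix - cbind(diag(2), c(0, 0)))), 1e-9)
  path <- withr::local_tempfile(fileext = ".json")
  write_affine_json(m, path)
  m2 <- read_affine_json(path)
  expect_equal(m2$matrix, m$matrix, tolerance = 1e-12)
})
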