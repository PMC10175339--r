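# Landmark-driven ROI geometry, detection, tracking, and the selection operator.

test_that("the nostril ROI follows the landmark geometry formula", {
  lm1 <- landmarks5(c(80, 60), c(120, 60), c(100, 100), c(90, 120), c(110, 120))
  r1 <- roi_from_landmarks(lm1)
  expect_identical(c(r1$eta, r1$omega), c(6, 10))
  expect_identical(c(r1$bx, r1$by, r1$w, r1$h), c(90, 94, 20, 18))
  lm2 <- landmarks5(c(40, 30), c(60, 30), c(50, 50), c(46, 58), c(54, 58))
  r2 <- roi_from_landmarks(lm2)
  expect_identical(c(r2$eta, r2$omega), c(2, 4))
  expect_identical(c(r2$bx, r2$by, r2$w, r2$h), c(46, 48, 8, 6))
  # degenerate geometry: coincident mouth corners
  lmd <- landmarks5(c(40, 30), c(60, 30), c(50, 50), c(50, 58), c(50, 58))
  expect_error(roi_from_landmarks(lmd), "degenerate")
  # property: w = 2*omega and h = 3*eta before clipping
  for (seed in 1:10) {
    p <- with_seed_local(seed, runif(6, 20, 200))
    lm <- landmarks5(c(p[1] - 30, p[2] - 40), c(p[1] + 30, p[2] - 40),
                     c(p[1], p[2]), c(p[1] - p[3] / 2, p[2] + p[4]),
                     c(p[1] + p[3] / 2, p[2] + p[4]))
    r <- roi_from_landmarks(lm)
    expect_identical(r$w, 2 * r$omega)
    expect_identical(r$h, 3 * r$eta)
  }
})

test_that("the fiducial detector locates planted landmarks within a pixel and fails on blank or occluded frames", {
  lm <- landmarks5(c(120, 80), c(200, 80), c(160, 120), c(130, 160), c(190, 160))
  fr <- fiducial_frame(lm)
  res <- detect_landmarks(fr, make_fiducial_detector())
  expect_true(res$d_s)
  for (nm in c("left_eye", "right_eye", "nose_tip", "mouth_left", "mouth_right")) {
    expect_lte(max(abs(res$landmarks[[nm]] - lm[[nm]])), 1)
  }
  # blank frame
  blank <- fiducial_frame(lm, blank = TRUE)
  expect_false(detect_landmarks(blank, make_fiducial_detector())$d_s)
  # partial occlusion of one marker drops confidence below the threshold
  occ <- fr
  occ[(120 - 1):(120 + 2) + 1, (160 - 2):(160 + 2) + 1] <- 0.4  # most of the nose cross
  expect_false(detect_landmarks(occ, make_fiducial_detector())$d_s)
  # a throwing detector is a failed detection, not an error
  expect_false(detect_landmarks(fr, function(f) stop("boom"))$d_s)
})

test_that("the correlation tracker holds a static target, follows motion, and fails when the target vanishes", {
  lm <- landmarks5(c(120, 80), c(200, 80), c(160, 120), c(130, 160), c(190, 160))
  # static scene: textured box
  base <- fiducial_frame(lm, seed = 9)
  box <- roi_box(140, 110, 40, 30)
  trk <- tracker_init(base, box)
  for (i in 1:30) {
    st <- tracker_step(trk, base)
    trk <- st$tracker
    expect_true(st$t_s)
  }
  expect_lte(abs(st$box$bx - box$bx), 1)
  expect_lte(abs(st$box$by - box$by), 1)
  # moving target: shift the whole frame 2 px/frame rightward
  trk <- tracker_init(base, box)
  for (k in 1:8) {
    shifted <- cbind(base[, rep(1, 2 * k)], base[, 1:(ncol(base) - 2 * k)])
    st <- tracker_step(trk, shifted)
    trk <- st$tracker
    expect_true(st$t_s)
    expect_lte(abs(st$box$bx - (box$bx + 2 * k)), 3)
    expect_lte(abs(st$box$by - box$by), 3)
  }
  # target vanishes: flat frames collapse the quality within 5 frames
  flat <- matrix(0.5, nrow(base), ncol(base))
  lost_at <- NA
  for (k in 1:5) {
    st <- tracker_step(trk, flat)
    trk <- st$tracker
    if (!st$t_s) { lost_at <- k; break }
  }
  expect_lte(lost_at, 5)
  # uninitialised tracker reports failure
  expect_false(tracker_step(NULL, base)$t_s)
})

test_that("the selection operator follows the tracking/detection truth table", {
  lm <- landmarks5(c(120, 80), c(200, 80), c(160, 120), c(130, 160), c(190, 160))
  good <- fiducial_frame(lm, seed = 9)
  flat <- matrix(0.5, 240, 320)  # kills both the tracker and the detector
  cases <- list(
    list(frame = good, det_fail = FALSE, want_t = TRUE, want_d = TRUE,
         want_mode = "tracking", want_roi = TRUE),
    list(frame = good, det_fail = TRUE, want_t = TRUE, want_d = FALSE,
         want_mode = "detecting", want_roi = FALSE),
    list(frame = flat, det_fail = FALSE, want_t = FALSE, want_d = TRUE,
         want_mode = "detecting", want_roi = TRUE),
    list(frame = flat, det_fail = TRUE, want_t = FALSE, want_d = FALSE,
         want_mode = "detecting", want_roi = FALSE))
  for (cs in cases) {
    # put the loop into tracking mode on a clean first frame
    det1 <- if (cs$det_fail) {
      scripted_detector(lm, fail_frames = 2L)
    } else if (identical(cs$frame, flat)) {
      scripted_detector(lm)  # detection scripted to succeed on the flat frame
    } else {
      make_fiducial_detector()
    }
    state <- td_init()
    state <- td_step(state, good, det1, frame_id = 1L)
    expect_identical(state$mode, "tracking")
    state <- td_step(state, cs$frame, det1, frame_id = 2L)
    expect_identical(state$t_s, cs$want_t)
    expect_identical(state$d_s, cs$want_d)
    expect_identical(state$mode, cs$want_mode)
    expect_identical(!is.na(state$log[[2]]$bx), cs$want_roi)
  }
})

test_that("a detection outage logs none-frames, then the tracker is reinitialised, and the success rate is the exact fraction", {
  lm <- landmarks5(c(120, 80), c(200, 80), c(160, 120), c(130, 160), c(190, 160))
  fr <- fiducial_frame(lm, seed = 9)
  det <- scripted_detector(lm, fail_frames = 5:14)
  state <- td_init()
  for (i in 1:30) state <- td_step(state, fr, det, frame_id = i)
  log <- td_log(state)
  expect_true(all(is.na(log$bx[5:14])))
  expect_true(all(!is.na(log$bx[c(1:4, 15:30)])))
  expect_identical(log$mode[15], "detecting")
  expect_identical(log$mode[16], "tracking")
  expect_identical(roi_success_rate(log), 100 * 20 / 30)
  expect_error(roi_success_rate(log[0, ]), "empty")
})

test_that("roi_success_rate reproduces the direct ratio", {
  mk <- function(n_ok, n_total) {
    tibble::tibble(frame_id = seq_len(n_total),
                   bx = c(rep(1, n_ok), rep(NA_real_, n_total - n_ok)))
  }
  expect_identical(roi_success_rate(mk(999, 1000)), 99.9)
  expect_identical(roi_success_rate(mk(1000, 1000)), 100)
  expect_identical(roi_success_rate(mk(0, 10)), 0)
})

test_that("the pipeline reacquires the ROI after an occlusion event without manual input", {
  spec <- scene_spec(duration_s = 12, seed = 12,
                     motion = list(list(type = "occlude", from = 5, to = 7)))
  sc <- generate_scene(spec)
  log <- run_td(sc$seq$rgb_frame, sc$seq$n_frames, make_fiducial_detector())
  occ <- which(sc$truth$occluded)
  expect_true(all(is.na(log$bx[occ])))
  post <- (max(occ) + 2):min(max(occ) + 20, nrow(log))
  expect_true(all(!is.na(log$bx[post])))
  expect_equal(roi_success_rate(log), 100 * mean(!sc$truth$occluded),
               tolerance = 1)
})
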