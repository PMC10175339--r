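# Ground-truthed synthetic RGB-T scene generator.
#
# Emulates the dual-camera acquisition geometry: a 960x720 visible stream with
# planted fiducial landmarks and a 320x240 thermal stream whose nostril-region
# temperature oscillates at the breathing frequency, the two related by a known
# affine map, plus checkerboard rig frames and optional motion/occlusion
# events. Everything derives from a single seed.

#' Constant-rate breathing waveform
#' @param rate_bpm Breathing rate (breaths per minute).
#' @return A `breathing_waveform`: list of `value(t)` in `[-1, 1]` and
#'   `rate_bpm(t)`.
#' @export
breathing_constant <- function(rate_bpm) {
  stopifnot(rate_bpm > 6, rate_bpm < 120)
  f <- rate_bpm / 60
  structure(list(value = function(t) sin(2 * pi * f * t),
                 rate_bpm = function(t) rep(rate_bpm, length(t)),
                 segments = list(list(duration_s = Inf, rate_bpm = rate_bpm))),
            class = "breathing_waveform")
}

#' Piecewise breathing waveform (varying rates and pauses)
#'
#' Builds a phase-continuous piecewise sinusoid: each segment either breathes
#' at a fixed rate or pauses. A pause freezes the phase and decays the
#' waveform toward zero (time constant `pause_tau` seconds), so there is no
#' step discontinuity at segment joins; the following rate segment resumes
#' from the decayed value.
#'
#' @param segments List of `list(duration_s =, rate_bpm =)`; use
#'   `rate_bpm = 0` (or `"pause"`) for a breath pause.
#' @param pause_tau Amplitude decay time constant during pauses (seconds).
#' @return A `breathing_waveform`.
#' @export
mode_c_waveform <- function(segments, pause_tau = 2) {
  segs <- lapply(segments, function(s) {
    r <- s$rate_bpm
    if (identical(r, "pause")) r <- 0
    stopifnot(s$duration_s > 0, r == 0 || (r > 6 && r < 120))
    list(duration_s = s$duration_s, rate_bpm = r)
  })
  starts <- cumsum(c(0, vapply(segs, `[[`, 0, "duration_s")))
  n <- length(segs)
  # phase and value at each segment start, chained for continuity
  phi0 <- numeric(n)
  for (i in seq_len(n - 1L)) {
    s <- segs[[i]]
    if (s$rate_bpm > 0) {
      phi_end <- phi0[i] + 2 * pi * (s$rate_bpm / 60) * s$duration_s
      v_end <- sin(phi_end)
    } else {
      v_end <- sin(phi0[i]) * exp(-s$duration_s / pause_tau)
      phi_end <- asin(max(-1, min(1, v_end)))  # resume rising through v_end
    }
    phi0[i + 1L] <- if (segs[[i + 1L]]$rate_bpm > 0) {
      if (s$rate_bpm > 0) phi_end else asin(max(-1, min(1, v_end)))
    } else phi_end
  }
  seg_of <- function(t) pmin(findInterval(t, starts, left.open = FALSE), n)
  value <- function(t) {
    si <- seg_of(t)
    out <- numeric(length(t))
    for (i in unique(si)) {
      sel <- si == i
      dt <- t[sel] - starts[i]
      s <- segs[[i]]
      out[sel] <- if (s$rate_bpm > 0) {
        sin(phi0[i] + 2 * pi * (s$rate_bpm / 60) * dt)
      } else {
        sin(phi0[i]) * exp(-dt / pause_tau)
      }
    }
    out
  }
  rate_bpm <- function(t) {
    vapply(seg_of(t), function(i) segs[[i]]$rate_bpm, 0)
  }
  structure(list(value = value, rate_bpm = rate_bpm, segments = segs,
                 starts = starts),
            class = "breathing_waveform")
}

#' Synthetic RGB-T scene specification
#'
#' Defaults mirror the acquisition geometry of the dual-camera setup this
#' package targets: 30 fps, 960x720 visible, 320x240 thermal, a scale-1/3
#' visible-to-thermal similarity, a 0.3 degC nostril temperature oscillation
#' on a 33 degC baseline over a 28 degC background, and thermal sensor noise
#' of 0.05 degC.
#'
#' @param duration_s Recording length (seconds).
#' @param fps Frame rate (both streams).
#' @param rgb_shape,thermal_shape Frame dimensions `c(nrow, ncol)`.
#' @param true_map The ground-truth visible-to-thermal [affine_map()].
#' @param waveform A `breathing_waveform`.
#' @param amplitude Nostril temperature oscillation amplitude (degC).
#' @param nostril_baseline,face_temp,ambient Temperatures (degC).
#' @param noise_sd Thermal per-pixel Gaussian noise SD (degC).
#' @param visible_noise_sd Visible per-pixel noise SD (on the `[0, 1]` scale).
#' @param landmarks A [landmarks5()] giving the face layout at rest (visible
#'   coordinates); `NULL` uses a centred default face.
#' @param motion List of events: `list(type = "translate", from =, to =,
#'   vx =, vy =)` (visible px/s) or `list(type = "occlude", from =, to =)`.
#' @param n_objects Number of static structural objects (discs/squares)
#'   rendered coherently in both modalities (registration texture).
#' @param rig_dims Inner-corner grid of the calibration rig.
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(duration_s, fps = 30, rgb_shape = c(720L, 960L),
                       thermal_shape = c(240L, 320L),
                       true_map = affine_similarity(1 / 3, 0, 2, 1),
                       waveform = breathing_constant(48), amplitude = 0.3,
                       nostril_baseline = 33, face_temp = 34, ambient = 28,
                       noise_sd = 0.05, visible_noise_sd = 0.002,
                       landmarks = NULL, motion = list(), n_objects = 25L,
                       rig_dims = c(6L, 5L), seed) {
  if (missing(seed)) stop("scene_spec requires a seed", call. = FALSE)
  stopifnot(duration_s > 0, fps > 0, inherits(waveform, "breathing_waveform"))
  rates <- waveform$rate_bpm(seq(0, duration_s, by = 1))
  if (any(rates / 60 >= fps / 2)) {
    stop("breathing rate violates the thermal Nyquist limit", call. = FALSE)
  }
  if (is.null(landmarks)) {
    cx <- rgb_shape[2] / 2; cy <- rgb_shape[1] / 2
    landmarks <- landmarks5(left_eye = c(cx - 50, cy - 60),
                            right_eye = c(cx + 50, cy - 60),
                            nose_tip = c(cx, cy),
                            mouth_left = c(cx - 46, cy + 60),
                            mouth_right = c(cx + 46, cy + 60))
  }
  structure(list(duration_s = duration_s, fps = fps, rgb_shape = rgb_shape,
                 thermal_shape = thermal_shape, true_map = true_map,
                 waveform = waveform, amplitude = amplitude,
                 nostril_baseline = nostril_baseline, face_temp = face_temp,
                 ambient = ambient, noise_sd = noise_sd,
                 visible_noise_sd = visible_noise_sd, landmarks = landmarks,
                 motion = motion, n_objects = as.integer(n_objects),
                 rig_dims = rig_dims, seed = as.integer(seed)),
            class = "scene_spec")
}

# Smooth random field: coarse uniform grid, bilinearly upsampled.
#' @noRd
smooth_field <- function(shape, coarse = c(24L, 32L), lo = 0.25, hi = 0.55) {
  g <- matrix(stats::runif(prod(coarse), lo, hi), coarse[1], coarse[2])
  ry <- seq(1, coarse[1], length.out = shape[1])
  rx <- seq(1, coarse[2], length.out = shape[2])
  y0 <- pmin(floor(ry), coarse[1] - 1L); x0 <- pmin(floor(rx), coarse[2] - 1L)
  fy <- ry - y0; fx <- rx - x0
  a <- g[cbind(rep(y0, length(x0)), rep(x0, each = length(y0)))]
  b <- g[cbind(rep(y0, length(x0)), rep(x0 + 1L, each = length(y0)))]
  cc <- g[cbind(rep(y0 + 1L, length(x0)), rep(x0, each = length(y0)))]
  d <- g[cbind(rep(y0 + 1L, length(x0)), rep(x0 + 1L, each = length(y0)))]
  FY <- rep(fy, length(x0)); FX <- rep(fx, each = length(y0))
  matrix((1 - FY) * ((1 - FX) * a + FX * b) + FY * ((1 - FX) * cc + FX * d),
         shape[1], shape[2])
}

# Draw a filled disc / rotated square into img (in place value assignment).
#' @noRd
draw_disc <- function(img, cx, cy, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(floor(cx - r), 0); x1 <- min(ceiling(cx + r), nc - 1)
  y0 <- max(floor(cy - r), 0); y1 <- min(ceiling(cy + r), nr - 1)
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  DX <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  DY <- matrix(ys - cy, length(ys), length(xs))
  mask <- DX^2 + DY^2 <= r^2
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[mask] <- value
  img[ys + 1L, xs + 1L] <- sub
  img
}

#' @noRd
draw_square <- function(img, cx, cy, half, rot, value) {
  nr <- nrow(img); nc <- ncol(img)
  rad <- half * sqrt(2)
  x0 <- max(floor(cx - rad), 0); x1 <- min(ceiling(cx + rad), nc - 1)
  y0 <- max(floor(cy - rad), 0); y1 <- min(ceiling(cy + rad), nr - 1)
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  DX <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  DY <- matrix(ys - cy, length(ys), length(xs))
  U <- cos(rot) * DX + sin(rot) * DY
  V <- -sin(rot) * DX + cos(rot) * DY
  mask <- abs(U) <= half & abs(V) <= half
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[mask] <- value
  img[ys + 1L, xs + 1L] <- sub
  img
}

# Sample static structural objects (shared between modalities).
#' @noRd
sample_objects <- function(n, rgb_shape, exclude_bbox) {
  objs <- list()
  tries <- 0L
  while (length(objs) < n && tries < n * 50L) {
    tries <- tries + 1L
    cx <- stats::runif(1, 0.05, 0.95) * rgb_shape[2]
    cy <- stats::runif(1, 0.05, 0.95) * rgb_shape[1]
    if (cx > exclude_bbox[1] - 30 && cx < exclude_bbox[2] + 30 &&
        cy > exclude_bbox[3] - 30 && cy < exclude_bbox[4] + 30) next
    objs[[length(objs) + 1L]] <- list(
      kind = sample(c("disc", "square"), 1L),
      cx = cx, cy = cy, size = stats::runif(1, 8, 45),
      rot = stats::runif(1, 0, pi / 2),
      shade = sample(c(0.08, 0.85), 1L))
  }
  objs
}

#' @noRd
render_objects_rgb <- function(img, objs) {
  for (ob in objs) {
    img <- if (ob$kind == "disc") {
      draw_disc(img, ob$cx, ob$cy, ob$size, ob$shade)
    } else {
      draw_square(img, ob$cx, ob$cy, ob$size, ob$rot, ob$shade)
    }
  }
  img
}

# Render the same objects in thermal coordinates (similarity-mapped geometry,
# inverted contrast: visually dark objects are warm, bright objects cool).
#' @noRd
render_objects_thermal <- function(img, objs, true_map, ambient) {
  A <- true_map$matrix[, 1:2]
  s <- sqrt(abs(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]))
  rot_extra <- atan2(A[2, 1], A[1, 1])
  for (ob in objs) {
    p <- apply_affine(true_map, cbind(ob$cx, ob$cy))
    temp <- ambient + if (ob$shade < 0.5) 3.5 else -2.5
    img <- if (ob$kind == "disc") {
      draw_disc(img, p[1], p[2], ob$size * s, temp)
    } else {
      draw_square(img, p[1], p[2], ob$size * s, ob$rot + rot_extra, temp)
    }
  }
  img
}

# Ellipse mask indices (0-based bbox + logical mask).
#' @noRd
ellipse_mask <- function(cx, cy, ax, ay, shape) {
  x0 <- max(floor(cx - ax), 0); x1 <- min(ceiling(cx + ax), shape[2] - 1)
  y0 <- max(floor(cy - ay), 0); y1 <- min(ceiling(cy + ay), shape[1] - 1)
  xs <- x0:x1; ys <- y0:y1
  DX <- matrix((xs - cx) / ax, length(ys), length(xs), byrow = TRUE)
  DY <- matrix((ys - cy) / ay, length(ys), length(xs))
  list(x0 = x0, y0 = y0, mask = DX^2 + DY^2 <= 1)
}

# Cumulative face displacement (visible px) at each frame time.
#' @noRd
motion_displacement <- function(motion, times) {
  d <- matrix(0, length(times), 2L)
  for (ev in motion) {
    if (!identical(ev$type, "translate")) next
    dt <- pmax(pmin(times, ev$to) - ev$from, 0)
    d[, 1] <- d[, 1] + dt * (ev$vx %||% 0)
    d[, 2] <- d[, 2] + dt * (ev$vy %||% 0)
  }
  d
}

#' @noRd
occluded_at <- function(motion, t) {
  for (ev in motion) {
    if (identical(ev$type, "occlude") && t >= ev$from && t < ev$to) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic RGB-T scene
#'
#' Renders (lazily, frame by frame) a paired visible/thermal recording: the
#' visible stream carries a textured face ellipse with five intensity-coded
#' fiducial landmarks and static structural objects; the thermal stream
#' carries the same geometry through `true_map`, with a warm face whose
#' nostril patch oscillates as
#' `baseline + amplitude * waveform(t) + noise`. Motion events translate the
#' face coherently in both streams; occlusion events hide it (flat block in
#' the visible stream, patch cooled to ambient in the thermal). Fully
#' deterministic given the spec seed.
#'
#' @param spec A [scene_spec()].
#' @return List with `seq` (an `rgbt_sequence`: `rgb_frame(i)`,
#'   `thermal_frame(i)`, `n_frames`, `fps`, shapes) and `truth` (a
#'   `ground_truth`: per-frame landmark matrix, occlusion flags, `true_map`,
#'   the true visible/thermal nostril boxes at rest, and
#'   `rr_of_window(start, end)`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n_frames <- as.integer(round(spec$duration_s * spec$fps))
  times <- (seq_len(n_frames) - 1) / spec$fps
  lm <- spec$landmarks
  nose <- lm$nose_tip
  face_ax <- 2.4 * abs(lm$mouth_right[1] - lm$mouth_left[1]) / 2
  face_ay <- 2.2 * abs(lm$mouth_left[2] - lm$left_eye[2])
  face_bbox <- c(nose[1] - face_ax, nose[1] + face_ax,
                 nose[2] - face_ay, nose[2] + face_ay)

  statics <- with_seed(spec$seed, {
    # per-frame noise seeds drawn from the master stream: arithmetically
    # derived (linearly related) seeds give weakly correlated Mersenne-Twister
    # streams, which show up as spurious coherent spectral lines in the
    # frame-to-frame noise means
    vis_seeds <- sample.int(2147483000L, n_frames)
    th_seeds <- sample.int(2147483000L, n_frames)
    bg <- smooth_field(spec$rgb_shape)
    objs <- sample_objects(spec$n_objects, spec$rgb_shape, face_bbox)
    bg <- render_objects_rgb(bg, objs)
    fm <- ellipse_mask(nose[1], nose[2], face_ax, face_ay, spec$rgb_shape)
    tex <- smooth_field(c(nrow(fm$mask), ncol(fm$mask)),
                        coarse = c(16L, 16L), lo = 0.55, hi = 0.8)
    tbg <- matrix(spec$ambient, spec$thermal_shape[1], spec$thermal_shape[2])
    tbg <- render_objects_thermal(tbg, objs, spec$true_map, spec$ambient)
    fc_t <- apply_affine(spec$true_map, rbind(nose))
    A <- spec$true_map$matrix[, 1:2]
    s <- sqrt(abs(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]))
    fmt <- ellipse_mask(fc_t[1], fc_t[2], face_ax * s, face_ay * s,
                        spec$thermal_shape)
    list(bg = bg, objs = objs, face_mask = fm, face_tex = tex,
         thermal_bg = tbg, thermal_face_mask = fmt, scale = s,
         vis_seeds = vis_seeds, th_seeds = th_seeds)
  })

  roi_vis <- roi_from_landmarks(lm, frame_shape = spec$rgb_shape)
  nostril_thermal <- map_roi(roi_vis, spec$true_map, spec$thermal_shape)

  disp <- motion_displacement(spec$motion, times)
  occ <- vapply(times, function(t) occluded_at(spec$motion, t), TRUE)
  lms <- cbind(le_x = lm$left_eye[1] + disp[, 1], le_y = lm$left_eye[2] + disp[, 2],
               re_x = lm$right_eye[1] + disp[, 1], re_y = lm$right_eye[2] + disp[, 2],
               n_x = nose[1] + disp[, 1], n_y = nose[2] + disp[, 2],
               ml_x = lm$mouth_left[1] + disp[, 1], ml_y = lm$mouth_left[2] + disp[, 2],
               mr_x = lm$mouth_right[1] + disp[, 1], mr_y = lm$mouth_right[2] + disp[, 2])

  levels <- fiducial_levels()
  marker_off <- cbind(c(0, 1, -1, 0, 0, 2, -2, 0, 0),
                      c(0, 0, 0, 1, -1, 0, 0, 2, -2))

  shift_mask_box <- function(x0, y0, mask, dx, dy, shape) {
    # shift the mask's bbox by integer (dx, dy), cropping at frame borders
    nx0 <- x0 + dx; ny0 <- y0 + dy
    h <- nrow(mask); w <- ncol(mask)
    cx0 <- max(nx0, 0); cy0 <- max(ny0, 0)
    cx1 <- min(nx0 + w, shape[2]); cy1 <- min(ny0 + h, shape[1])
    if (cx1 <= cx0 || cy1 <= cy0) return(NULL)
    list(rows = (cy0 + 1):cy1, cols = (cx0 + 1):cx1,
         mask = mask[(cy0 - ny0 + 1):(cy1 - ny0), (cx0 - nx0 + 1):(cx1 - nx0),
                     drop = FALSE])
  }

  rgb_frame <- function(i) {
    t <- times[i]
    dx <- round(disp[i, 1]); dy <- round(disp[i, 2])
    fr <- statics$bg
    sh <- shift_mask_box(statics$face_mask$x0, statics$face_mask$y0,
                         statics$face_mask$mask, dx, dy, spec$rgb_shape)
    if (!is.null(sh)) {
      texc <- statics$face_tex[seq_along(sh$rows) + (max(0, -(statics$face_mask$y0 + dy))),
                               seq_along(sh$cols) + (max(0, -(statics$face_mask$x0 + dx))),
                               drop = FALSE]
      sub <- fr[sh$rows, sh$cols, drop = FALSE]
      sub[sh$mask] <- texc[sh$mask]
      fr[sh$rows, sh$cols] <- sub
    }
    if (!occ[i]) {
      for (nm in names(levels)) {
        p <- switch(nm, left_eye = lms[i, 1:2], right_eye = lms[i, 3:4],
                    nose_tip = lms[i, 5:6], mouth_left = lms[i, 7:8],
                    mouth_right = lms[i, 9:10])
        mx <- round(p[1]) + marker_off[, 1]
        my <- round(p[2]) + marker_off[, 2]
        ok <- mx >= 0 & my >= 0 & mx < spec$rgb_shape[2] & my < spec$rgb_shape[1]
        fr[cbind(my[ok] + 1L, mx[ok] + 1L)] <- levels[[nm]]
      }
    } else {
      x0 <- max(round(face_bbox[1] + dx), 0); x1 <- min(round(face_bbox[2] + dx), spec$rgb_shape[2] - 1)
      y0 <- max(round(face_bbox[3] + dy), 0); y1 <- min(round(face_bbox[4] + dy), spec$rgb_shape[1] - 1)
      if (x1 >= x0 && y1 >= y0) fr[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- 0.5
    }
    if (spec$visible_noise_sd > 0) {
      # uniform noise of the stated sd: an 8-bit sensor under good light is
      # quantisation-dominated, and uniform variates are cheap per frame
      a <- spec$visible_noise_sd * sqrt(3)
      fr <- fr + with_seed(statics$vis_seeds[i],
                           matrix(stats::runif(length(fr), -a, a), nrow(fr)))
    }
    fr
  }

  A <- spec$true_map$matrix[, 1:2]
  thermal_frame <- function(i) {
    t <- times[i]
    dt_xy <- round(A %*% disp[i, ])
    fr <- statics$thermal_bg
    sh <- shift_mask_box(statics$thermal_face_mask$x0, statics$thermal_face_mask$y0,
                         statics$thermal_face_mask$mask, dt_xy[1], dt_xy[2],
                         spec$thermal_shape)
    if (!is.null(sh)) {
      sub <- fr[sh$rows, sh$cols, drop = FALSE]
      sub[sh$mask] <- spec$face_temp
      fr[sh$rows, sh$cols] <- sub
    }
    if (!occ[i]) {
      bx <- nostril_thermal$bx + dt_xy[1]; by <- nostril_thermal$by + dt_xy[2]
      rows <- max(by + 1, 1):min(by + nostril_thermal$h, spec$thermal_shape[1])
      cols <- max(bx + 1, 1):min(bx + nostril_thermal$w, spec$thermal_shape[2])
      if (length(rows) > 0 && length(cols) > 0) {
        fr[rows, cols] <- spec$nostril_baseline +
          spec$amplitude * spec$waveform$value(t)
      }
    }
    if (spec$noise_sd > 0) {
      fr <- fr + with_seed(statics$th_seeds[i],
                           matrix(stats::rnorm(length(fr), 0, spec$noise_sd),
                                  nrow(fr)))
    }
    fr
  }

  seq_obj <- structure(list(rgb_frame = rgb_frame, thermal_frame = thermal_frame,
                            n_frames = n_frames, fps = spec$fps,
                            rgb_shape = spec$rgb_shape,
                            thermal_shape = spec$thermal_shape),
                       class = "rgbt_sequence")
  truth <- structure(list(
    landmarks = lms, occluded = occ, true_map = spec$true_map,
    roi_visible = roi_vis, nostril_thermal = nostril_thermal,
    rate_bpm = spec$waveform$rate_bpm, waveform = spec$waveform,
    rr_of_window = function(start, end) {
      tt <- seq(start, end, by = 1 / spec$fps)
      mean(spec$waveform$rate_bpm(tt))
    },
    spec = spec), class = "ground_truth")
  list(seq = seq_obj, truth = truth)
}

#' Render a checkerboard calibration-rig frame pair
#'
#' The rig (a square-cut checkerboard of a poorly heat-conducting material) is
#' rendered in the visible frame and, with inverted contrast, in the thermal
#' frame through `true_map`.
#'
#' @param true_map Ground-truth visible-to-thermal [affine_map()].
#' @param rig_dims Inner-corner grid `c(rows, cols)`.
#' @param rgb_shape,thermal_shape Frame dimensions.
#' @param square_px Checker square side in visible pixels.
#' @param noise_sd Per-pixel noise SD added to both renderings.
#' @param seed Integer seed.
#' @return List: `rgb`, `thermal`, `true_map`, and the true inner-corner
#'   coordinates `corners_rgb` (continuous, row-major).
#' @export
generate_rig_pair <- function(true_map, rig_dims = c(6L, 5L),
                              rgb_shape = c(720L, 960L),
                              thermal_shape = c(240L, 320L),
                              square_px = 72, noise_sd = 0.005, seed = 1L) {
  rows <- rig_dims[1]; cols <- rig_dims[2]
  stopifnot(rows >= 3, cols >= 3)
  board_w <- (cols + 1) * square_px
  board_h <- (rows + 1) * square_px
  # centre the board on the region that maps into the thermal frame
  centre_t <- c(thermal_shape[2] / 2, thermal_shape[1] / 2)
  centre_v <- apply_affine(invert_affine(true_map), rbind(centre_t))
  ox <- centre_v[1] - board_w / 2
  oy <- centre_v[2] - board_h / 2

  board_value <- function(u, v, dark, light, outside) {
    iu <- floor((u - ox) / square_px)
    iv <- floor((v - oy) / square_px)
    inside <- iu >= 0 & iv >= 0 & iu <= cols & iv <= rows
    val <- ifelse((iu + iv) %% 2 == 0, light, dark)
    val[!inside] <- outside
    val
  }
  xs_v <- rep(0:(rgb_shape[2] - 1), each = rgb_shape[1])
  ys_v <- rep(0:(rgb_shape[1] - 1), times = rgb_shape[2])
  rgb <- matrix(board_value(xs_v, ys_v, 0.15, 0.9, 0.5),
                rgb_shape[1], rgb_shape[2])
  xs_t <- rep(0:(thermal_shape[2] - 1), each = thermal_shape[1])
  ys_t <- rep(0:(thermal_shape[1] - 1), times = thermal_shape[2])
  pv <- apply_affine(invert_affine(true_map), cbind(xs_t, ys_t))
  thermal <- matrix(board_value(pv[, 1], pv[, 2], 31.5, 26.5, 28.5),
                    thermal_shape[1], thermal_shape[2])
  if (noise_sd > 0) {
    with_seed(seed, {
      rgb <- rgb + matrix(stats::rnorm(length(rgb), 0, noise_sd), nrow(rgb))
      thermal <- thermal + matrix(stats::rnorm(length(thermal), 0, noise_sd * 10),
                                  nrow(thermal))
    })
  }
  # with sampling at integer pixel centres, the corner response peaks half a
  # pixel before the cell boundary
  cx <- ox + square_px * (1:cols) - 0.5
  cy <- oy + square_px * (1:rows) - 0.5
  corners <- cbind(x = rep(cx, times = rows), y = rep(cy, each = cols))
  list(rgb = rgb, thermal = thermal, true_map = true_map,
       corners_rgb = corners)
}

#' Render a structured (non-face) scene pair for registration tests
#'
#' Discs and squares at random positions, rendered analytically in each
#' modality (inverted contrast in the thermal one) so the two frames are
#' related exactly by `true_map` with no interpolation error.
#'
#' @param true_map Ground-truth visible-to-thermal [affine_map()].
#' @param rgb_shape,thermal_shape Frame dimensions.
#' @param n_objects Number of objects.
#' @param noise_sd Per-pixel noise SD (visible scale; thermal noise is 10x,
#'   matching its degC dynamic range).
#' @param seed Integer seed.
#' @return List: `rgb`, `thermal`, `true_map`.
#' @export
generate_structured_pair <- function(true_map, rgb_shape = c(720L, 960L),
                                     thermal_shape = c(240L, 320L),
                                     n_objects = 40L, noise_sd = 0.005,
                                     seed = 1L) {
  with_seed(seed, {
    # objects placed in the visible region that maps into the thermal frame
    tc <- rbind(c(0, 0), c(thermal_shape[2], 0), c(0, thermal_shape[1]),
                c(thermal_shape[2], thermal_shape[1]))
    vc <- apply_affine(invert_affine(true_map), tc)
    xr <- range(vc[, 1]); yr <- range(vc[, 2])
    objs <- lapply(seq_len(n_objects), function(j) {
      list(kind = sample(c("disc", "square"), 1L),
           cx = stats::runif(1, xr[1] + 40, xr[2] - 40),
           cy = stats::runif(1, yr[1] + 40, yr[2] - 40),
           size = stats::runif(1, 6, 36), rot = stats::runif(1, 0, pi / 2),
           shade = sample(c(0.1, 0.9), 1L))
    })
    rgb <- matrix(0.45, rgb_shape[1], rgb_shape[2])
    rgb <- render_objects_rgb(rgb, objs)
    thermal <- matrix(28, thermal_shape[1], thermal_shape[2])
    thermal <- render_objects_thermal(thermal, objs, true_map, 28)
    rgb <- rgb + matrix(stats::rnorm(length(rgb), 0, noise_sd), nrow(rgb))
    thermal <- thermal + matrix(stats::rnorm(length(thermal), 0, noise_sd * 10),
                                nrow(thermal))
    list(rgb = rgb, thermal = thermal, true_map = true_map)
  })
}
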