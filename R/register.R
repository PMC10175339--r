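#' Registration parameters
#'
#' Tunables of the phase-congruency refinement stage.
#'
#' @param lg [log_gabor_params()] for the feature stage.
#' @param fast_threshold FAST contrast threshold on normalised moment maps.
#' @param max_points Maximum keypoints per image.
#' @param patch_size Descriptor patch side (pixels, rough-thermal coordinates).
#' @param grid Descriptor cells per side.
#' @param nndr Nearest-neighbour distance-ratio threshold.
#' @param fsc_iterations Number of fast-sample-consensus samples.
#' @param inlier_tol FSC inlier tolerance (thermal pixels).
#' @param seed Integer seed for the consensus sampler.
#' @return A `register_params` list.
#' @export
register_params <- function(lg = log_gabor_params(), fast_threshold = 0.08,
                            max_points = 500L, patch_size = 72L, grid = 6L,
                            nndr = 0.85, fsc_iterations = 2000L,
                            inlier_tol = 2, seed = 1L) {
  structure(list(lg = lg, fast_threshold = fast_threshold,
                 max_points = as.integer(max_points),
                 patch_size = as.integer(patch_size), grid = as.integer(grid),
                 nndr = nndr, fsc_iterations = as.integer(fsc_iterations),
                 inlier_tol = inlier_tol, seed = as.integer(seed)),
            class = "register_params")
}

# Phase-congruency feature extraction for one image: keypoints + descriptors.
#' @noRd
pc_features_for <- function(img, params, bank = NULL) {
  if (is.null(bank)) bank <- build_log_gabor_bank(dim(img), params$lg)
  resp <- filter_responses(img, bank)
  pc <- phase_congruency(resp)
  mom <- moment_maps(pc)
  kps <- detect_keypoints(mom, fast_threshold = params$fast_threshold,
                          max_points = params$max_points)
  if (nrow(kps) == 0L) return(list(keypoints = kps, descriptors = NULL))
  oim <- orientation_index_map(resp)
  d <- describe_keypoints(oim, kps, patch_size = params$patch_size,
                          grid = params$grid)
  list(keypoints = d$keypoints, descriptors = d$descriptors)
}

#' Two-phase visible-to-thermal registration
#'
#' Refines a rig-based similarity map with phase-congruency keypoint
#' registration: the visible frame is resampled into rough thermal coordinates
#' using `rig_map`, phase congruency and moment maps are computed on both
#' images, FAST keypoints are described by orientation-index histograms,
#' matched by SSD with the NNDR test, and a precise affine map is fitted by
#' fast sample consensus. The result is the precise map composed with
#' `rig_map`, mapping visible pixels directly to thermal pixels.
#'
#' @param rgb_frame Visible frame (numeric matrix, single channel).
#' @param thermal_frame Thermal frame (numeric matrix).
#' @param rig_map An [affine_map()] from [scale_adjust_from_rig()], or `NULL`
#'   when the frames are already in a common scale.
#' @param params A [register_params()] object.
#' @return An [affine_map()] with `provenance = "composed"`.
#' @export
register_rgbt <- function(rgb_frame, thermal_frame, rig_map = NULL,
                          params = register_params()) {
  assert_image(rgb_frame, "rgb_frame", min_dim = 16L)
  assert_image(thermal_frame, "thermal_frame", min_dim = 16L)
  if (is.null(rig_map)) rig_map <- affine_identity(provenance = "rig")
  rough <- warp_image(rgb_frame, invert_affine(rig_map), dim(thermal_frame))

  bank <- build_log_gabor_bank(dim(thermal_frame), params$lg)
  fa <- pc_features_for(rough, params, bank)
  fb <- pc_features_for(thermal_frame, params, bank)
  if (is.null(fa$descriptors) || nrow(fa$keypoints) == 0L) {
    stop_registration("keypoints", "no keypoints in the (warped) visible frame")
  }
  if (is.null(fb$descriptors) || nrow(fb$keypoints) == 0L) {
    stop_registration("keypoints", "no keypoints in the thermal frame")
  }
  ms <- match_descriptors(fa$descriptors, fb$descriptors, nndr = params$nndr)
  if (nrow(ms$pairs) < 3L) {
    stop_registration("matching", sprintf("only %d matches (need >= 3)", nrow(ms$pairs)))
  }
  precise <- estimate_affine_fsc(ms, fa$keypoints, fb$keypoints,
                                 iterations = params$fsc_iterations,
                                 inlier_tol = params$inlier_tol,
                                 seed = params$seed)
  compose_affine(precise, rig_map, provenance = "composed")
}
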