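# FAST keypoints on moment maps, orientation-index descriptors, SSD/NNDR matching.

# 16-point Bresenham circle of radius 3 (dx = column offset, dy = row offset),
# in circular order.
fast_circle <- cbind(
  dx = c(0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L, -3L, -3L, -2L, -1L),
  dy = c(-3L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L))

# FAST segment test on one normalized map. Returns tibble of x, y (0-based), score.
#' @noRd
fast_on_map <- function(map, threshold, arc_len = 12L) {
  nr <- nrow(map); nc <- ncol(map)
  if (nr < 8L || nc < 8L) return(tibble::tibble(x = integer(), y = integer(), score = numeric()))
  rows <- 4:(nr - 3); cols <- 4:(nc - 3)
  centre <- map[rows, cols]
  npx <- length(centre)
  circ <- matrix(0, npx, 16L)
  for (j in 1:16) {
    circ[, j] <- as.vector(map[rows + fast_circle[j, "dy"], cols + fast_circle[j, "dx"]])
  }
  cvec <- as.vector(centre)
  bright <- circ > cvec + threshold
  dark <- circ < cvec - threshold
  # contiguous circular arc of >= arc_len
  has_arc <- function(b) {
    bd <- cbind(b, b[, seq_len(arc_len - 1L), drop = FALSE])
    acc <- rep(FALSE, nrow(b))
    cs <- t(apply(bd, 1L, cumsum))
    for (s in 1:16) {
      tot <- cs[, s + arc_len - 1L] - (if (s == 1L) 0 else cs[, s - 1L])
      acc <- acc | (tot == arc_len)
    }
    acc
  }
  is_corner <- has_arc(bright) | has_arc(dark)
  if (!any(is_corner)) return(tibble::tibble(x = integer(), y = integer(), score = numeric()))
  score_vec <- rowSums(pmax(abs(circ - cvec) - threshold, 0))
  score_map <- matrix(0, nr, nc)
  sm_inner <- matrix(0, length(rows), length(cols))
  sm_inner[is_corner] <- score_vec[is_corner]
  score_map[rows, cols] <- sm_inner
  # 3x3 non-maximum suppression
  keep <- score_map > 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    shifted <- matrix(0, nr, nc)
    src_r <- max(1, 1 - dy):min(nr, nr - dy)
    src_c <- max(1, 1 - dx):min(nc, nc - dx)
    shifted[src_r + dy, src_c + dx] <- score_map[src_r, src_c]
    keep <- keep & (score_map >= shifted)
  }
  idx <- which(keep)
  tibble::tibble(x = (idx - 1L) %/% nr, y = (idx - 1L) %% nr,
                 score = score_map[idx])
}

#' Detect keypoints on the moment maps
#'
#' Runs the FAST segment test (contiguous arc of 12 on a 16-pixel Bresenham
#' circle, with 3x3 non-maximum suppression) on the min-max-normalised maximum
#' and minimum moment maps and keeps the strongest responses.
#'
#' @param moments A [moment_maps()] object.
#' @param fast_threshold Intensity contrast threshold on the normalised maps.
#' @param max_points Maximum number of keypoints returned (by score).
#' @return Tibble with columns `x`, `y` (0-based pixel coordinates), `source`
#'   (`"maximum"` or `"minimum"` moment map) and `score`. May be empty.
#' @export
detect_keypoints <- function(moments, fast_threshold = 0.08, max_points = 500L) {
  stopifnot(inherits(moments, "moment_maps"))
  if (!all(is.finite(moments$M)) || !all(is.finite(moments$m))) {
    stop("moment maps contain non-finite values", call. = FALSE)
  }
  kM <- fast_on_map(minmax_norm(moments$M), fast_threshold)
  km <- fast_on_map(minmax_norm(moments$m), fast_threshold)
  kM$source <- rep("maximum", nrow(kM))
  km$source <- rep("minimum", nrow(km))
  kps <- dplyr::bind_rows(kM, km)
  kps <- kps[order(-kps$score), , drop = FALSE]
  kps <- utils::head(kps, max_points)
  kps[, c("x", "y", "source", "score")]
}

#' Orientation-index histogram descriptors
#'
#' SIFT-like descriptor built from the dominant-orientation index map: the
#' square patch around each keypoint is divided into `grid x grid` cells and
#' each cell contributes an `n_orientations`-bin histogram of the index values,
#' weighted by the summed filter amplitude; the concatenation is L2-normalised.
#' Keypoints whose patch leaves the image, or whose descriptor is all-zero,
#' are dropped.
#'
#' @param oim An [orientation_index_map()].
#' @param kps Keypoint tibble from [detect_keypoints()].
#' @param patch_size Patch side (pixels); must be a multiple of `grid`.
#' @param grid Cells per patch side.
#' @return List with `descriptors` (matrix, one row per kept keypoint, row
#'   length `grid^2 * n_orientations`) and `keypoints` (the kept rows of `kps`).
#' @export
describe_keypoints <- function(oim, kps, patch_size = 72L, grid = 6L) {
  stopifnot(inherits(oim, "orientation_index_map"))
  if (patch_size %% grid != 0L || patch_size %% 2L != 0L) {
    stop("patch_size must be an even multiple of grid", call. = FALSE)
  }
  half <- patch_size %/% 2L
  cell <- patch_size %/% grid
  nr <- oim$shape[1]; nc <- oim$shape[2]
  no <- oim$n_orientations
  len <- grid * grid * no
  # cell id for every pixel of a patch (column-major over the patch)
  px <- rep(0:(patch_size - 1L), each = patch_size)   # x offset
  py <- rep(0:(patch_size - 1L), times = patch_size)  # y offset
  cell_id <- (px %/% cell) * grid + (py %/% cell)     # 0-based

  keep <- logical(nrow(kps))
  descs <- matrix(0, nrow(kps), len)
  for (i in seq_len(nrow(kps))) {
    x0 <- kps$x[i] - half; y0 <- kps$y[i] - half
    if (x0 < 0L || y0 < 0L || x0 + patch_size > nc || y0 + patch_size > nr) next
    rows <- (y0 + 1L):(y0 + patch_size)
    cols <- (x0 + 1L):(x0 + patch_size)
    idx <- as.vector(oim$index[rows, cols])
    amp <- as.vector(oim$max_amplitude[rows, cols])
    bin <- cell_id * no + (idx - 1L) + 1L  # 1-based position in descriptor
    v <- numeric(len)
    acc <- rowsum(amp, bin)
    v[as.integer(rownames(acc))] <- acc[, 1]
    nrm <- sqrt(sum(v^2))
    if (nrm <= 0) next
    descs[i, ] <- v / nrm
    keep[i] <- TRUE
  }
  list(descriptors = descs[keep, , drop = FALSE],
       keypoints = kps[keep, , drop = FALSE])
}

#' Match descriptors by SSD with the nearest-neighbour distance ratio test
#'
#' For each descriptor in `a`, the nearest and second-nearest descriptors in
#' `b` (sum of squared differences) are found; the pair is kept when
#' `d1 < nndr * d2`, and matches are made one-to-one by mutual-best filtering.
#'
#' @param a,b Descriptor matrices (rows are descriptors).
#' @param nndr Distance-ratio threshold in `(0, 1]`; `1` disables ratio pruning.
#' @return Object of class `match_set`: tibble `pairs` with `index_a`,
#'   `index_b`, `ssd_distance`, plus the threshold used.
#' @export
match_descriptors <- function(a, b, nndr = 0.85) {
  stopifnot(is.numeric(nndr), nndr > 0, nndr <= 1)
  empty <- structure(list(pairs = tibble::tibble(index_a = integer(),
                                                 index_b = integer(),
                                                 ssd_distance = numeric()),
                          nndr_threshold = nndr),
                     class = "match_set")
  if (is.null(dim(a)) || is.null(dim(b)) || nrow(a) < 2L || nrow(b) < 2L) {
    return(empty)
  }
  D <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  D <- pmax(D, 0)
  j1 <- max.col(-D, ties.method = "first")
  d1 <- D[cbind(seq_len(nrow(a)), j1)]
  D2 <- D
  D2[cbind(seq_len(nrow(a)), j1)] <- Inf
  d2 <- D2[cbind(seq_len(nrow(a)), max.col(-D2, ties.method = "first"))]
  pass <- d1 < nndr * d2 + 1e-12
  # mutual best: a_i's best b must have a_i as its best a
  besta_for_b <- apply(D, 2L, which.min)
  mutual <- besta_for_b[j1] == seq_len(nrow(a))
  keep <- which(pass & mutual)
  structure(list(pairs = tibble::tibble(index_a = keep, index_b = j1[keep],
                                        ssd_distance = d1[keep]),
                 nndr_threshold = nndr),
            class = "match_set")
}
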