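# FAST segment-test corner detection, vectorized over whole frames.
# The matcher downstream is detector-agnostic (matching never uses
# descriptors), so the standard FAST-9 test with non-maximum suppression is
# used as the pluggable default detector.

PATCH_SIZE <- 16L
PATCH_HALF <- 8L

# Bresenham circle of radius 3: 16 (du, dv) ring offsets in order.
fast_ring <- cbind(
  du = c(0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L, -3L, -3L, -2L, -1L),
  dv = c(-3L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
)

#' Detect corner features with the FAST-9 segment test
#'
#' A pixel is a corner when at least 9 contiguous pixels on its radius-3
#' Bresenham ring are all brighter than the centre plus `threshold`, or all
#' darker than the centre minus `threshold`. Corners are scored by the summed
#' ring contrast beyond the threshold and thinned by greedy non-maximum
#' suppression. Features closer than 8 px to any border are discarded so
#' that a full 16x16 patch fits around each returned position.
#'
#' @param image grayscale matrix in `[0, 1]`, larger than 16x16.
#' @param threshold intensity difference of the segment test (default 0.08).
#' @param nonmax_radius suppression radius in pixels: of any two corners
#'   closer than this, only the higher-scoring one survives.
#' @return A data frame with 0-based pixel columns `u`, `v` and `score`,
#'   ordered by decreasing score.
#' @export
detect_features <- function(image, threshold = 0.08, nonmax_radius = 8) {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  if (H <= PATCH_SIZE || W <= PATCH_SIZE)
    stop("image too small: need more than 16x16 pixels")
  m <- PATCH_HALF  # interior margin; also covers the ring radius 3
  # interior pixel block, 0-based v in [m, H-1-m], u in [m, W-1-m]
  vi <- (m + 1):(H - m); ui <- (m + 1):(W - m)  # 1-based rows/cols
  C <- image[vi, ui]
  hi <- C + threshold; lo <- C - threshold
  nr <- length(vi); nc <- length(ui)
  bright <- vector("list", 16); dark <- vector("list", 16)
  for (k in 1:16) {
    S <- image[vi + fast_ring[k, "dv"], ui + fast_ring[k, "du"]]
    bright[[k]] <- S > hi
    dark[[k]] <- S < lo
  }
  corner <- matrix(FALSE, nr, nc)
  for (masks in list(bright, dark)) {
    for (s in 1:16) {
      acc <- masks[[s]]
      for (j in 1:8) {
        if (!any(acc)) break
        acc <- acc & masks[[(s + j - 1L) %% 16L + 1L]]
      }
      corner <- corner | acc
    }
  }
  idx <- which(corner)
  if (length(idx) == 0)
    return(data.frame(u = numeric(0), v = numeric(0), score = numeric(0)))
  # score: summed absolute ring contrast beyond the threshold
  score <- matrix(0, nr, nc)
  for (k in 1:16) {
    S <- image[vi + fast_ring[k, "dv"], ui + fast_ring[k, "du"]]
    score <- score + pmax(0, abs(S - C) - threshold)
  }
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  u <- ui[cc] - 1L  # back to 0-based full-image coordinates
  v <- vi[rr] - 1L
  sc <- score[idx]
  ord <- order(-sc, v, u)  # deterministic: score desc, then position
  u <- u[ord]; v <- v[ord]; sc <- sc[ord]
  keep <- logical(length(u))
  r2 <- nonmax_radius^2
  for (i in seq_along(u)) {
    if (i > 1) {
      prev <- which(keep[seq_len(i - 1)])
      if (length(prev) &&
          any((u[prev] - u[i])^2 + (v[prev] - v[i])^2 < r2)) next
    }
    keep[i] <- TRUE
  }
  data.frame(u = as.numeric(u[keep]), v = as.numeric(v[keep]),
             score = sc[keep])
}

#' Extract the 16x16 patch centred on a feature
#'
#' The feature pixel sits at patch index `(8, 8)` (0-based): the patch
#' covers the half-open pixel window `[v - 8, v + 8) x [u - 8, u + 8)`.
#' Intensities are returned as stored (frames are normalized to `[0, 1]`).
#'
#' @param image grayscale matrix.
#' @param position length-2 vector `(u, v)`, 0-based integer pixel position.
#' @return A 16x16 numeric matrix.
#' @export
extract_patch <- function(image, position) {
  stopifnot(is.matrix(image), length(position) == 2)
  u <- as.integer(round(position[1])); v <- as.integer(round(position[2]))
  H <- nrow(image); W <- ncol(image)
  if (v - PATCH_HALF < 0 || v + PATCH_HALF - 1 > H - 1 ||
      u - PATCH_HALF < 0 || u + PATCH_HALF - 1 > W - 1)
    stop("patch out of bounds at (", u, ", ", v, ")")
  image[(v - PATCH_HALF + 1):(v + PATCH_HALF), (u - PATCH_HALF + 1):(u + PATCH_HALF)]
}

#' Stack patches for a set of feature positions
#'
#' @param image grayscale matrix.
#' @param positions `n x 2` matrix or data frame with columns `u`, `v`.
#' @return A `16 x 16 x n` array of patches.
#' @export
patch_stack <- function(image, positions) {
  if (is.data.frame(positions)) positions <- cbind(positions$u, positions$v)
  positions <- as_point_matrix(positions, 2)$m
  n <- nrow(positions)
  out <- array(0, dim = c(PATCH_SIZE, PATCH_SIZE, n))
  for (i in seq_len(n)) out[, , i] <- extract_patch(image, positions[i, ])
  out
}
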