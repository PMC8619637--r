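#' Parallel binocular camera parameters
#'
#' Bundles the geometry of a rectified parallel stereo rig: both optical axes
#' are parallel, the baseline joins the optical centres, and corresponding
#' image points share the same vertical coordinate so only horizontal
#' parallax carries depth. Camera-plane coordinates are metric (same unit as
#' `focal_length` and `baseline`, millimetres by convention); pixels are
#' converted through `pixel_size`.
#'
#' @param focal_length focal length of both cameras (mm), `> 0`.
#' @param baseline distance between the optical centres (mm), `> 0`.
#' @param principal_point `(cx, cy)` in 0-based pixel coordinates.
#' @param pixel_size metric side length of one pixel (mm/pixel), `> 0`.
#' @param vertical_tolerance maximum accepted `|yl - yr|` (camera-plane mm)
#'   for a stereo pair; defaults to two pixels. Must be `>= 0`.
#'
#' @return An object of class `stereo_camera`.
#' @examples
#' cam <- stereo_camera(focal_length = 1, baseline = 0.99,
#'                      principal_point = c(159.5, 159.5),
#'                      pixel_size = 0.0015)
#' @export
stereo_camera <- function(focal_length, baseline, principal_point,
                          pixel_size, vertical_tolerance = 2 * pixel_size) {
  stopifnot(is.numeric(focal_length), length(focal_length) == 1,
            is.numeric(baseline), length(baseline) == 1,
            is.numeric(principal_point), length(principal_point) == 2,
            is.numeric(pixel_size), length(pixel_size) == 1,
            is.numeric(vertical_tolerance), length(vertical_tolerance) == 1)
  if (focal_length <= 0) stop("focal_length must be > 0")
  if (baseline <= 0) stop("baseline must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (vertical_tolerance < 0) stop("vertical_tolerance must be >= 0")
  structure(list(focal_length = focal_length,
                 baseline = baseline,
                 principal_point = as.numeric(principal_point),
                 pixel_size = pixel_size,
                 vertical_tolerance = vertical_tolerance),
            class = "stereo_camera")
}

#' @export
print.stereo_camera <- function(x, ...) {
  cat(sprintf("<stereo_camera> f = %g, b = %g, pp = (%g, %g) px, pixel = %g, vtol = %g\n",
              x$focal_length, x$baseline, x$principal_point[1],
              x$principal_point[2], x$pixel_size, x$vertical_tolerance))
  invisible(x)
}

# Accept a length-2/3 vector or an n x k matrix; return a matrix plus a flag
# so single points round-trip back to vectors.
as_point_matrix <- function(p, k) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == k)
    list(m = matrix(as.numeric(p), ncol = k), vec = TRUE)
  } else {
    m <- as.matrix(p)
    stopifnot(ncol(m) == k)
    list(m = m, vec = FALSE)
  }
}

restore_shape <- function(m, vec) if (vec) drop(m) else m

#' Convert pixel coordinates to metric camera-plane coordinates
#'
#' `pixel_to_camera()` maps 0-based pixel positions `(u, v)` to metric
#' camera-plane coordinates `(x, y)` with the origin at the principal point;
#' `camera_to_pixel()` is its exact inverse.
#'
#' @param p a length-2 vector `(u, v)` (or `(x, y)`), or an `n x 2` matrix.
#' @param cam a [stereo_camera()].
#' @return Coordinates with the same shape as `p`.
#' @examples
#' cam <- stereo_camera(1, 0.99, c(100, 100), 0.01)
#' pixel_to_camera(c(150, 100), cam)  # (0.5, 0)
#' @export
pixel_to_camera <- function(p, cam) {
  stopifnot(inherits(cam, "stereo_camera"))
  pp <- as_point_matrix(p, 2)
  m <- cbind((pp$m[, 1] - cam$principal_point[1]) * cam$pixel_size,
             (pp$m[, 2] - cam$principal_point[2]) * cam$pixel_size)
  restore_shape(m, pp$vec)
}

#' @rdname pixel_to_camera
#' @export
camera_to_pixel <- function(p, cam) {
  stopifnot(inherits(cam, "stereo_camera"))
  pp <- as_point_matrix(p, 2)
  m <- cbind(pp$m[, 1] / cam$pixel_size + cam$principal_point[1],
             pp$m[, 2] / cam$pixel_size + cam$principal_point[2])
  restore_shape(m, pp$vec)
}

#' A matched pair of left/right image points
#'
#' Positions are metric camera-plane coordinates (origin at the principal
#' point of each view). For a rectified rig corresponding points share their
#' vertical coordinate up to the camera's `vertical_tolerance`.
#'
#' @param left,right length-2 vectors `(x, y)` or `n x 2` matrices.
#' @return An object of class `image_point_pair` holding `left` and `right`
#'   as `n x 2` matrices (single pairs are kept as 1-row matrices).
#' @export
image_point_pair <- function(left, right) {
  l <- as_point_matrix(left, 2)
  r <- as_point_matrix(right, 2)
  stopifnot(nrow(l$m) == nrow(r$m))
  structure(list(left = l$m, right = r$m), class = "image_point_pair")
}

#' Horizontal disparity of a stereo pair
#'
#' `d = xl - xr`, computed on demand (never stored) from the pair.
#'
#' @param pair an [image_point_pair()].
#' @return Numeric vector of disparities (camera-plane units).
#' @export
disparity <- function(pair) {
  stopifnot(inherits(pair, "image_point_pair"))
  pair$left[, 1] - pair$right[, 1]
}

#' Project 3D points onto a rectified stereo pair
#'
#' Applies the similar-triangle projection of the parallel rig:
#' `xl = f X / Z`, `xr = f (X - b) / Z`, `yl = yr = f Y / Z`.
#'
#' @param P a length-3 vector `(X, Y, Z)` or `n x 3` matrix in the left
#'   camera frame; all `Z` must be `> 0`.
#' @param cam a [stereo_camera()].
#' @return An [image_point_pair()] in metric camera-plane coordinates.
#' @examples
#' cam <- stereo_camera(1, 1, c(0, 0), 0.01)
#' project_point(c(1, 1, 1), cam)  # left (1,1), right (0,1)
#' @export
project_point <- function(P, cam) {
  stopifnot(inherits(cam, "stereo_camera"))
  pp <- as_point_matrix(P, 3)
  Z <- pp$m[, 3]
  if (any(Z <= 0)) stop("invalid depth: all Z must be > 0 for projection")
  f <- cam$focal_length
  xl <- f * pp$m[, 1] / Z
  xr <- f * (pp$m[, 1] - cam$baseline) / Z
  y <- f * pp$m[, 2] / Z
  image_point_pair(cbind(xl, y), cbind(xr, y))
}

#' Rectified epipolar gate
#'
#' For a rectified parallel rig the epipolar constraint degenerates to equal
#' vertical coordinates; a pair is accepted when `|yl - yr|` does not exceed
#' the camera's `vertical_tolerance` (inclusive bound).
#'
#' @inheritParams disparity
#' @param cam a [stereo_camera()].
#' @return Logical vector, `TRUE` for accepted pairs.
#' @export
epipolar_gate <- function(pair, cam) {
  stopifnot(inherits(pair, "image_point_pair"), inherits(cam, "stereo_camera"))
  abs(pair$left[, 2] - pair$right[, 2]) <= cam$vertical_tolerance
}

#' Recover 3D coordinates from a matched stereo pair
#'
#' Inverts the rectified projection through the disparity `d = xl - xr`:
#' `X = b xl / d`, `Y = b y / d`, `Z = b f / d`, with `y = (yl + yr) / 2`
#' (exact when rectified, symmetric averaging of residual vertical noise
#' otherwise). Pairs must pass the epipolar gate and have positive disparity.
#'
#' @inheritParams epipolar_gate
#' @return A length-3 vector for a single pair, or an `n x 3` matrix.
#' @examples
#' cam <- stereo_camera(1, 0.99, c(0, 0), 0.01)
#' recover_point3d(image_point_pair(c(0.5, 0.2), c(0.1, 0.2)), cam)
#' # (1.2375, 0.495, 2.475)
#' @export
recover_point3d <- function(pair, cam) {
  stopifnot(inherits(pair, "image_point_pair"), inherits(cam, "stereo_camera"))
  if (!all(epipolar_gate(pair, cam)))
    stop("epipolar violation: |yl - yr| exceeds vertical_tolerance")
  d <- disparity(pair)
  if (any(d <= 0))
    stop("nonpositive disparity: point at infinity or behind the camera")
  b <- cam$baseline
  y <- (pair$left[, 2] + pair$right[, 2]) / 2
  m <- cbind(X = b * pair$left[, 1] / d,
             Y = b * y / d,
             Z = b * cam$focal_length / d)
  if (nrow(m) == 1) drop(m) else m
}
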