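# Seeded generator of rectified stereo sequences of a blob-textured,
# periodically deforming surface with full ground truth. The default scene
# mirrors the reference acquisition where numbers are printed: 52 markers,
# 25 fps, an 18.75-frame period (80 cycles per minute), focal length 1 mm
# and baseline 0.99 mm; depth-oscillation amplitudes use the reported Z
# ranges (0.02 mm regular / 0.1 mm irregular) while lateral amplitudes are
# scaled to stay inside the synthetic field of view. Geometry is chosen so
# the nominal disparity is ~66 px, keeping integer-pixel detection noise
# well below 2 percent of depth. Rendering ignores occlusion and
# perspective patch distortion (endoscope scenes show little of either);
# each marker carries a distinct multi-Gaussian contrast pattern so a patch
# classifier can separate the categories.

#' Configure a synthetic deforming-surface stereo scene
#'
#' @param n_markers number of surface markers (including the irregular one
#'   when `irregular_marker` is `TRUE`).
#' @param image_size `(width, height)` in pixels.
#' @param cam a [stereo_camera()]; the default matches the reference rig
#'   (f = 1 mm, b = 0.99 mm) with a 1.5 um pixel.
#' @param base_depth resting surface depth (mm).
#' @param lateral_amplitude sinusoidal X/Y amplitude of regular markers
#'   (mm); the peak-to-peak range is twice this.
#' @param depth_amplitude sinusoidal Z amplitude of regular markers (mm).
#' @param irregular_marker add one marker driven by smoothed noise with
#'   `irregular_scale` times the regular amplitudes (emulating a locally
#'   irregular tissue region).
#' @param irregular_scale amplitude multiplier of the irregular marker.
#' @param frequency deformation rate in cycles per second; the default
#'   4/3 Hz at 25 fps gives a period of 18.75 frames (80 per minute).
#' @param fps frame rate (frames per second).
#' @param n_frames number of frames to render.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param phase_jitter per-marker phase jitter (radians) around the common
#'   deformation phase.
#' @param seed RNG seed; identical configurations produce bit-identical
#'   scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_markers = 52,
                         image_size = c(320, 320),
                         cam = stereo_camera(focal_length = 1, baseline = 0.99,
                                             principal_point = (image_size - 1) / 2,
                                             pixel_size = 0.0015),
                         base_depth = 10,
                         lateral_amplitude = 0.15,
                         depth_amplitude = 0.01,
                         irregular_marker = TRUE,
                         irregular_scale = 2,
                         frequency = 4 / 3,
                         fps = 25,
                         n_frames = 60,
                         noise_sigma = 0,
                         phase_jitter = 0.25,
                         seed = 1) {
  stopifnot(n_markers >= 1, base_depth > 0, fps > 0, n_frames >= 1,
            noise_sigma >= 0, frequency > 0)
  structure(list(n_markers = as.integer(n_markers),
                 image_size = as.integer(image_size), cam = cam,
                 base_depth = base_depth,
                 lateral_amplitude = lateral_amplitude,
                 depth_amplitude = depth_amplitude,
                 irregular_marker = irregular_marker,
                 irregular_scale = irregular_scale,
                 frequency = frequency, fps = fps,
                 n_frames = as.integer(n_frames),
                 noise_sigma = noise_sigma,
                 phase_jitter = phase_jitter,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Gaussian smoothing of a white-noise path, rescaled so the excursion stays
# within `amplitude` and the per-frame step within `step_max` (so the
# aperiodic marker remains trackable by nearest-neighbour chaining); used
# for the irregular marker's wander.
smoothed_noise_path <- function(n, amplitude, sigma_frames = 6,
                                step_max = amplitude / 4) {
  z <- rnorm(n + 8 * sigma_frames)
  k <- dnorm(seq(-4 * sigma_frames, 4 * sigma_frames), sd = sigma_frames)
  s <- stats::filter(z, k / sum(k), sides = 2)
  s <- s[seq.int(4 * sigma_frames + 1, 4 * sigma_frames + n)]
  s <- s - mean(s)
  m <- max(abs(s)); dm <- max(abs(diff(s)))
  if (m == 0) return(rep(0, n))
  s * min(amplitude / m, if (dm > 0) step_max / dm else Inf)
}

# Distinct multi-Gaussian contrast pattern for one marker: a dominant
# central blob (detection anchor), 3-4 bright satellites and one dark blob
# at seeded positions, giving each marker a separable patch appearance.
draw_marker_pattern <- function() {
  n_sat <- sample(3:4, 1)
  sat <- data.frame(
    du = runif(n_sat, 3.2, 4.8) * cos(runif(n_sat, 0, 2 * pi)),
    dv = runif(n_sat, 3.2, 4.8) * sin(runif(n_sat, 0, 2 * pi)),
    amp = runif(n_sat, 0.1, 0.22),
    sigma = runif(n_sat, 0.8, 1.2))
  dark_r <- runif(1, 3.5, 5.0); dark_a <- runif(1, 0, 2 * pi)
  sat <- rbind(sat, data.frame(du = dark_r * cos(dark_a),
                               dv = dark_r * sin(dark_a),
                               amp = -runif(1, 0.05, 0.12),
                               sigma = runif(1, 1.2, 2.0)))
  list(amp0 = runif(1, 0.6, 0.8), sigma0 = runif(1, 1.2, 1.7), sat = sat)
}

render_pattern <- function(img, uc, vc, pat) {
  H <- nrow(img); W <- ncol(img)
  R <- 9L
  j0 <- max(1L, floor(uc) - R + 1L); j1 <- min(W, floor(uc) + R + 2L)
  i0 <- max(1L, floor(vc) - R + 1L); i1 <- min(H, floor(vc) + R + 2L)
  du <- ((j0:j1) - 1) - uc
  dv <- ((i0:i1) - 1) - vc
  D2u <- matrix(du^2, length(dv), length(du), byrow = TRUE)
  D2v <- matrix(dv^2, length(dv), length(du))
  add <- pat$amp0 * exp(-(D2u + D2v) / (2 * pat$sigma0^2))
  for (s in seq_len(nrow(pat$sat))) {
    d2 <- outer(dv - pat$sat$dv[s], du - pat$sat$du[s],
                function(a, b) a^2 + b^2)
    add <- add + pat$sat$amp[s] * exp(-d2 / (2 * pat$sat$sigma[s]^2))
  }
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + add
  img
}

#' Generate a synthetic rectified stereo sequence with ground truth
#'
#' Markers sit on a jittered grid at the base depth and oscillate as
#' `Z_m(t) = base_depth + A_m sin(2 pi freq t / fps + phi_m)` with
#' coherent-phase lateral X/Y sinusoids; one optional marker follows a
#' smoothed-noise (aperiodic) path. Frames are rendered as multi-Gaussian
#' blob patterns over a low-frequency background texture, identically in
#' both views via the rectified projection, plus optional Gaussian pixel
#' noise. The same configuration (including seed) is bit-reproducible.
#'
#' @param config a [scene_config()].
#' @return An object of class `stereo_scene`: list with `left` and `right`
#'   (lists of frame matrices), `truth` (list with per-frame/per-marker
#'   data frame `positions` holding `frame, marker, X, Y, Z, ul, vl, ur,
#'   vr, irregular`; `period_frames`; per-marker per-axis `ranges`;
#'   `markers`), and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  W <- config$image_size[1]; H <- config$image_size[2]
  cam <- config$cam
  n <- config$n_markers
  with_seed(config$seed, {
    # marker layout on an 8 x 8 pixel grid in the left view, keeping both
    # projections at least 12 px inside each image over the whole motion
    d_px <- cam$baseline * cam$focal_length /
      (config$base_depth * cam$pixel_size)
    irr_margin <- 23
    u_lo <- 12 + d_px + irr_margin; u_hi <- W - 13 - irr_margin
    grid_u <- seq(u_lo, u_hi, length.out = 8)
    grid_v <- seq(12 + irr_margin, H - 13 - irr_margin, length.out = 8)
    cells <- expand.grid(gu = seq_len(8), gv = seq_len(8))
    centre_cell <- which(cells$gu == 4 & cells$gv == 4)
    if (config$irregular_marker) {
      near <- which(abs(cells$gu - 4) <= 1 & abs(cells$gv - 4) <= 1)
      avail <- setdiff(seq_len(nrow(cells)), near)
      if (n - 1 > length(avail)) stop("too many markers for the layout grid")
      chosen <- c(avail[seq_len(n - 1)], centre_cell)
      irregular <- c(rep(FALSE, n - 1), TRUE)
    } else {
      if (n > nrow(cells)) stop("too many markers for the layout grid")
      chosen <- seq_len(n)
      irregular <- rep(FALSE, n)
    }
    ul0 <- grid_u[cells$gu[chosen]] + runif(n, -3, 3)
    vl0 <- grid_v[cells$gv[chosen]] + runif(n, -3, 3)
    # resting 3D position back-projected from the left-pixel grid
    xy_cam <- pixel_to_camera(cbind(ul0, vl0), cam)
    X0 <- xy_cam[, 1] * config$base_depth / cam$focal_length
    Y0 <- xy_cam[, 2] * config$base_depth / cam$focal_length
    Z0 <- rep(config$base_depth, n)

    phases <- runif(n, -config$phase_jitter, config$phase_jitter)
    patterns <- lapply(seq_len(n), function(i) draw_marker_pattern())

    # trajectories
    tt <- (seq_len(config$n_frames) - 1) / config$fps
    omega <- 2 * pi * config$frequency
    XT <- matrix(0, config$n_frames, n)
    YT <- matrix(0, config$n_frames, n)
    ZT <- matrix(0, config$n_frames, n)
    for (m in seq_len(n)) {
      if (irregular[m]) {
        a <- config$irregular_scale
        # cap lateral steps at ~3.5 px/frame so nearest-neighbour chaining
        # (link radius 5 px) keeps the aperiodic marker in one chain
        step_cap <- 3.5 * cam$pixel_size * config$base_depth / cam$focal_length
        XT[, m] <- X0[m] + smoothed_noise_path(config$n_frames,
                                               a * config$lateral_amplitude,
                                               step_max = step_cap)
        YT[, m] <- Y0[m] + smoothed_noise_path(config$n_frames,
                                               a * config$lateral_amplitude,
                                               step_max = step_cap)
        ZT[, m] <- Z0[m] + smoothed_noise_path(config$n_frames,
                                               5 * config$depth_amplitude)
      } else {
        XT[, m] <- X0[m] + config$lateral_amplitude * sin(omega * tt + phases[m])
        YT[, m] <- Y0[m] + config$lateral_amplitude * sin(omega * tt + phases[m] + 1.2)
        ZT[, m] <- Z0[m] + config$depth_amplitude * sin(omega * tt + phases[m])
      }
    }
    if (any(ZT <= 0)) stop("depth became non-positive during deformation")

    # static low-frequency background texture, identical in both views
    ug <- matrix(0:(W - 1), H, W, byrow = TRUE)
    vg <- matrix(0:(H - 1), H, W)
    bg <- matrix(0.18, H, W)
    for (j in 1:4) {
      p <- runif(1, -1, 1) / 80; q <- runif(1, -1, 1) / 80
      bg <- bg + runif(1, 0.008, 0.015) * cos(2 * pi * (p * ug + q * vg) +
                                              runif(1, 0, 2 * pi))
    }

    left <- vector("list", config$n_frames)
    right <- vector("list", config$n_frames)
    pos_rows <- vector("list", config$n_frames)
    for (f in seq_len(config$n_frames)) {
      P <- cbind(XT[f, ], YT[f, ], ZT[f, ])
      pr <- project_point(P, cam)
      lp <- camera_to_pixel(pr$left, cam)
      rp <- camera_to_pixel(pr$right, cam)
      bad <- which(lp[, 1] < 12 | lp[, 1] > W - 13 | lp[, 2] < 12 |
                   lp[, 2] > H - 13 | rp[, 1] < 12 | rp[, 1] > W - 13 |
                   rp[, 2] < 12 | rp[, 2] > H - 13)
      if (length(bad))
        stop("marker ", bad[1], " leaves the image at frame ", f)
      li <- bg; ri <- bg
      for (m in seq_len(n)) {
        li <- render_pattern(li, lp[m, 1], lp[m, 2], patterns[[m]])
        ri <- render_pattern(ri, rp[m, 1], rp[m, 2], patterns[[m]])
      }
      if (config$noise_sigma > 0) {
        li <- li + matrix(rnorm(H * W, sd = config$noise_sigma), H, W)
        ri <- ri + matrix(rnorm(H * W, sd = config$noise_sigma), H, W)
      }
      left[[f]] <- clamp01(li)
      right[[f]] <- clamp01(ri)
      pos_rows[[f]] <- data.frame(frame = f, marker = seq_len(n),
                                  X = P[, 1], Y = P[, 2], Z = P[, 3],
                                  ul = lp[, 1], vl = lp[, 2],
                                  ur = rp[, 1], vr = rp[, 2],
                                  irregular = irregular)
    }
    ranges <- data.frame(marker = seq_len(n),
                         X = apply(XT, 2, function(v) diff(range(v))),
                         Y = apply(YT, 2, function(v) diff(range(v))),
                         Z = apply(ZT, 2, function(v) diff(range(v))))
    structure(list(left = left, right = right,
                   truth = list(positions = do.call(rbind, pos_rows),
                                period_frames = config$fps / config$frequency,
                                ranges = ranges,
                                markers = data.frame(marker = seq_len(n),
                                                     ul0 = ul0, vl0 = vl0,
                                                     irregular = irregular)),
                   config = config),
              class = "stereo_scene")
  })
}

#' @export
print.stereo_scene <- function(x, ...) {
  cat(sprintf("<stereo_scene> %d markers, %d frames, %dx%d px, period %.2f frames\n",
              x$config$n_markers, x$config$n_frames, x$config$image_size[1],
              x$config$image_size[2], x$truth$period_frames))
  invisible(x)
}

#' Cut a labelled training-patch set from a scene
#'
#' Extracts the 16x16 patch at each marker's (rounded) ground-truth left
#' position in the first `first_k` frames, labelled by marker identity.
#' Positions whose patch would overrun the image border are excluded and
#' counted.
#'
#' @param scene a [generate_scene()] result.
#' @param first_k number of leading frames to use.
#' @return List with `patches` (`16 x 16 x N` array), `labels` (marker
#'   ids), `positions` (data frame `frame, marker, u, v`) and `n_excluded`.
#' @export
make_training_set <- function(scene, first_k) {
  stopifnot(inherits(scene, "stereo_scene"),
            first_k >= 1, first_k <= scene$config$n_frames)
  pos <- scene$truth$positions
  pos <- pos[pos$frame <= first_k, ]
  u <- round(pos$ul); v <- round(pos$vl)
  W <- scene$config$image_size[1]; H <- scene$config$image_size[2]
  ok <- u >= PATCH_HALF & u <= W - PATCH_HALF - 1 &
        v >= PATCH_HALF & v <= H - PATCH_HALF - 1
  patches <- array(0, dim = c(PATCH_SIZE, PATCH_SIZE, sum(ok)))
  idx <- which(ok)
  for (i in seq_along(idx))
    patches[, , i] <- extract_patch(scene$left[[pos$frame[idx[i]]]],
                                    c(u[idx[i]], v[idx[i]]))
  list(patches = patches, labels = pos$marker[ok],
       positions = data.frame(frame = pos$frame[ok], marker = pos$marker[ok],
                              u = u[ok], v = v[ok]),
       n_excluded = sum(!ok))
}

# Nearest ground-truth marker of each (u, v) position in a given frame;
# NA when none lies within tol_px.
nearest_marker <- function(scene, frame, u, v, tol_px) {
  gt <- scene$truth$positions
  gt <- gt[gt$frame == frame, ]
  vapply(seq_along(u), function(i) {
    d2 <- (gt$ul - u[i])^2 + (gt$vl - v[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol_px^2) gt$marker[j] else NA_integer_
  }, integer(1))
}

nearest_marker_right <- function(scene, frame, u, v, tol_px) {
  gt <- scene$truth$positions
  gt <- gt[gt$frame == frame, ]
  vapply(seq_along(u), function(i) {
    d2 <- (gt$ur - u[i])^2 + (gt$vr - v[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol_px^2) gt$marker[j] else NA_integer_
  }, integer(1))
}

#' Map feature categories to ground-truth markers
#'
#' Assigns each category's reference position (first frame, left image) to
#' the nearest ground-truth marker within `tol_px`.
#'
#' @param scene a [generate_scene()] result.
#' @param categories data frame with columns `category`, `u`, `v` (e.g.
#'   from [select_categories()]).
#' @param tol_px assignment tolerance in pixels.
#' @return Integer vector of marker ids (NA where unassigned), named by
#'   category.
#' @export
category_marker_map <- function(scene, categories, tol_px = 6) {
  m <- nearest_marker(scene, 1, categories$u, categories$v, tol_px)
  names(m) <- categories$category
  m
}

#' Score pipeline results against scene ground truth
#'
#' A match pair is correct when its left and right endpoints both lie
#' within `tol_px` of the projections of the same ground-truth marker.
#' Correct pairs additionally contribute a 3D error (recovered position vs
#' the marker's true 3D position). Track summaries compare the recovered
#' dominant period against the true deformation period.
#'
#' @param scene a [generate_scene()] result.
#' @param matches list of match data frames (as from [frame_matches()]).
#' @param frames integer vector: the scene frame number of each element of
#'   `matches`.
#' @param tracks optional named list of `feature_track`s to summarize.
#' @param tol_px endpoint tolerance in pixels.
#' @return List with `matching` (`accuracy` — NA with `accuracy_defined =
#'   FALSE` when no pairs exist — `n_pairs`, `n_correct`, `mean_error3d`,
#'   `error_pct_of_depth`, `per_marker_rmse`) and, when tracks are given,
#'   `tracks` (per track: blank fraction, [motion_summary()], period error
#'   in frames).
#' @export
evaluate_pipeline <- function(scene, matches, frames, tracks = NULL,
                              tol_px = 6) {
  stopifnot(inherits(scene, "stereo_scene"), length(matches) == length(frames))
  cam <- scene$config$cam
  gt <- scene$truth$positions
  n_pairs <- 0L; n_correct <- 0L
  err <- numeric(0); err_marker <- integer(0)
  for (i in seq_along(matches)) {
    m <- matches[[i]]
    if (nrow(m) == 0) next
    f <- frames[i]
    lm <- nearest_marker(scene, f, m$lu, m$lv, tol_px)
    rm_ <- nearest_marker_right(scene, f, m$ru, m$rv, tol_px)
    good <- !is.na(lm) & !is.na(rm_) & lm == rm_
    n_pairs <- n_pairs + nrow(m)
    n_correct <- n_correct + sum(good)
    for (j in which(good)) {
      pair <- image_point_pair(pixel_to_camera(c(m$lu[j], m$lv[j]), cam),
                               pixel_to_camera(c(m$ru[j], m$rv[j]), cam))
      if (!epipolar_gate(pair, cam) || disparity(pair) <= 0) next
      P <- recover_point3d(pair, cam)
      g <- gt[gt$frame == f & gt$marker == lm[j], ]
      err <- c(err, sqrt((P[1] - g$X)^2 + (P[2] - g$Y)^2 + (P[3] - g$Z)^2))
      err_marker <- c(err_marker, lm[j])
    }
  }
  mean_depth <- mean(gt$Z)
  matching <- list(
    accuracy = if (n_pairs > 0) n_correct / n_pairs else NA_real_,
    accuracy_defined = n_pairs > 0,
    n_pairs = n_pairs, n_correct = n_correct,
    mean_error3d = if (length(err)) mean(err) else NA_real_,
    error_pct_of_depth = if (length(err)) 100 * mean(err) / mean_depth
                         else NA_real_,
    per_marker_rmse = if (length(err))
      data.frame(marker = sort(unique(err_marker)),
                 rmse = vapply(sort(unique(err_marker)), function(mm)
                   sqrt(mean(err[err_marker == mm]^2)), numeric(1)))
      else NULL)
  out <- list(matching = matching)
  if (!is.null(tracks)) {
    out$tracks <- lapply(tracks, function(tr) {
      ms <- motion_summary(tr, fps = scene$config$fps)
      list(category = tr$category,
           blank_fraction = ms$blank_fraction,
           summary = ms,
           period_error_frames = if (is.na(ms$period_frames)) NA_real_
                                 else abs(ms$period_frames -
                                          scene$truth$period_frames))
    })
  }
  out
}

#' Write a scene to disk as PNG frames plus ground-truth files
#'
#' Frames go to `left/` and `right/` subdirectories as zero-padded PNGs,
#' the ground truth to `ground_truth.csv` and the configuration echo to
#' `scene.json`.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "stereo_scene"))
  dir.create(file.path(dir, "left"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "right"), recursive = TRUE, showWarnings = FALSE)
  nf <- scene$config$n_frames
  for (f in seq_len(nf)) {
    name <- sprintf("frame_%04d.png", f)
    write_frame(scene$left[[f]], file.path(dir, "left", name))
    write_frame(scene$right[[f]], file.path(dir, "right", name))
  }
  atomic_write(file.path(dir, "ground_truth.csv"), function(tmp)
    write.csv(scene$truth$positions, tmp, row.names = FALSE))
  cfg <- scene$config
  cfg$cam <- unclass(cfg$cam)
  atomic_write(file.path(dir, "scene.json"), function(tmp)
    jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}
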