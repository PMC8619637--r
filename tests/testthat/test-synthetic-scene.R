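test_that("identical configurations generate bit-identical scenes", {
  cfg <- scene_config(n_markers = 10, n_frames = 4, seed = 77,
                      noise_sigma = 0.01)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$left, s2$left)
  expect_identical(s1$right, s2$right)
  expect_identical(s1$truth$positions, s2$truth$positions)
})

test_that("the static limit produces identical frames and constant truth", {
  s <- generate_scene(scene_config(n_markers = 8, n_frames = 4,
                                   lateral_amplitude = 0, depth_amplitude = 0,
                                   irregular_marker = FALSE, noise_sigma = 0,
                                   seed = 5))
  expect_identical(s$left[[1]], s$left[[4]])
  expect_identical(s$right[[1]], s$right[[3]])
  pos <- s$truth$positions
  expect_equal(length(unique(pos$X[pos$marker == 3])), 1)
  expect_equal(length(unique(pos$Z[pos$marker == 5])), 1)
})

test_that("the default deformation clock gives 18.75 frames per cycle (80 per minute)", {
  cfg <- scene_config(n_frames = 2)
  expect_equal(cfg$fps / cfg$frequency, 18.75)
  s <- generate_scene(cfg)
  expect_equal(s$truth$period_frames, 18.75)
  expect_equal(60 * cfg$fps / s$truth$period_frames, 80)
})

test_that("ground truth is rectified and consistent with the camera model", {
  s <- generate_scene(scene_config(n_markers = 10, n_frames = 3, seed = 2))
  pos <- s$truth$positions
  expect_equal(pos$vl, pos$vr)  # yl == yr by construction
  cam <- s$config$cam
  # image positions recover the stored 3D positions with zero residual
  pair <- image_point_pair(pixel_to_camera(cbind(pos$ul, pos$vl), cam),
                           pixel_to_camera(cbind(pos$ur, pos$vr), cam))
  rec <- recover_point3d(pair, cam)
  expect_equal(unname(rec), unname(as.matrix(pos[, c("X", "Y", "Z")])),
               tolerance = 1e-12)
})

test_that("a marker that would leave the frame is reported by index and frame", {
  expect_error(generate_scene(scene_config(n_markers = 8, n_frames = 10,
                                           lateral_amplitude = 3, seed = 1)),
               "marker .* leaves the image at frame")
})

test_that("training sets carry one labelled patch per marker per frame", {
  s <- generate_scene(scene_config(n_markers = 10, n_frames = 6, seed = 3))
  ts <- make_training_set(s, first_k = 4)
  expect_equal(dim(ts$patches), c(16, 16, 4 * 10 - ts$n_excluded))
  expect_equal(ts$n_excluded, 0)  # layout keeps markers off the border
  expect_setequal(unique(ts$labels), 1:10)
  # distinct markers produce distinct patch content at zero noise
  p1 <- ts$patches[, , which(ts$labels == 1)[1]]
  p2 <- ts$patches[, , which(ts$labels == 2)[1]]
  expect_gt(max(abs(p1 - p2)), 0.05)
})

test_that("evaluation scores ground-truth correspondences as perfect", {
  s <- generate_scene(scene_config(n_markers = 10, n_frames = 3, seed = 4))
  gt <- s$truth$positions
  mk_matches <- function(f) {
    g <- gt[gt$frame == f, ]
    data.frame(category = g$marker, lu = g$ul, lv = g$vl,
               ru = g$ur, rv = g$vr)
  }
  ev <- evaluate_pipeline(s, lapply(1:3, mk_matches), 1:3)
  expect_equal(ev$matching$accuracy, 1)
  expect_equal(ev$matching$n_pairs, 30)
  expect_lt(ev$matching$mean_error3d, 1e-9)
  # swapping two markers' right endpoints loses exactly 2 pairs per frame
  swapped <- mk_matches(1)
  swapped$ru[1:2] <- swapped$ru[2:1]
  ev2 <- evaluate_pipeline(s, list(swapped), 1)
  expect_equal(ev2$matching$accuracy, 1 - 2 / 10)
  # no pairs at all: accuracy undefined, not an error
  none <- evaluate_pipeline(s, list(mk_matches(1)[0, ]), 1)
  expect_true(is.na(none$matching$accuracy))
  expect_false(none$matching$accuracy_defined)
})

test_that("scene export writes frames, ground truth and a manifest", {
  s <- generate_scene(scene_config(n_markers = 6, n_frames = 2,
                                   image_size = c(256, 256),
                                   cam = stereo_camera(1, 0.99, c(127.5, 127.5),
                                                       0.0015),
                                   seed = 8))
  dir <- tempfile("scene")
  write_scene(s, dir)
  pairs <- list_frame_pairs(file.path(dir, "left"), file.path(dir, "right"))
  expect_equal(nrow(pairs), 2)
  back <- read_frame(pairs$left[1])
  expect_equal(dim(back), c(256, 256))
  expect_lt(max(abs(back - s$left[[1]])), 1 / 255)  # 8-bit PNG quantization
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 12)
  manifest <- jsonlite::read_json(file.path(dir, "scene.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$n_markers, 6)
})
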