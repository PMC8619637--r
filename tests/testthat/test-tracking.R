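make_track <- function(xyz, status = NULL) {
  n <- nrow(xyz)
  status <- status %||% ifelse(is.na(xyz[, 1]), "blank", "observed")
  endorecon:::new_feature_track(1L, seq_len(n), xyz, status)
}
`%||%` <- endorecon:::`%||%`

test_that("gap filling takes the mean of adjacent observations", {
  xyz <- rbind(c(1, 2, 3), c(NA, NA, NA), c(3, 6, 9))
  tr <- fill_gaps(make_track(xyz))
  expect_equal(tr$xyz[2, ], c(X = 2, Y = 4, Z = 6), ignore_attr = TRUE)
  expect_equal(tr$status, c("observed", "filled", "observed"))
  # no blanks: identical track; leading blanks stay blank
  full <- make_track(rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_identical(fill_gaps(full), full)
  lead <- fill_gaps(make_track(rbind(c(NA, NA, NA), c(2, 2, 2), c(3, 3, 3))))
  expect_equal(lead$status[1], "blank")
  # idempotence, and observed entries never change
  tr2 <- fill_gaps(tr)
  expect_identical(tr2, tr)
})

test_that("consecutive blanks are filled progressively from both sides", {
  xyz <- rbind(c(0, 0, 0), c(NA, NA, NA), c(NA, NA, NA), c(6, 6, 6))
  tr <- fill_gaps(make_track(xyz))
  # left-to-right scan: entry 2 = mean(1, 4), entry 3 = mean(2, 4)
  expect_equal(unname(tr$xyz[2, ]), rep(3, 3))
  expect_equal(unname(tr$xyz[3, ]), rep(4.5, 3))
  expect_identical(fill_gaps(tr), tr)
})

test_that("tracking points are chosen nearest the category centroid", {
  cats <- data.frame(category = 1:4,
                     u = c(0, 10, 0, 10), v = c(0, 0, 10, 10))
  one <- select_tracking_points(rbind(cats, data.frame(category = 5, u = 6, v = 5)),
                                k = 1)
  expect_equal(one$category, 5)
  three <- select_tracking_points(cats, k = 3)
  expect_equal(three$label, c("a", "b", "c"))
  expect_equal(three$category, 1:3)  # all equidistant: ties by index
  expect_error(select_tracking_points(cats, k = 5), "fewer than k")
})

test_that("motion summaries recover ranges, period and rate", {
  # constant track: zero ranges, undefined period
  const <- make_track(matrix(1, 30, 3))
  ms0 <- motion_summary(const, fps = 25)
  expect_equal(unname(ms0$range), c(0, 0, 0))
  expect_true(is.na(ms0$period_frames))
  # sinusoid at the reference deformation rate: period 18.75 frames -> 80/min
  t <- 0:49
  A <- 1.5
  xyz <- cbind(A * sin(2 * pi * t / 18.75), 0, 0)
  ms <- motion_summary(make_track(xyz), fps = 25)
  expect_lte(abs(ms$period_frames - 18.75), 1)
  expect_lte(abs(ms$rate_per_min - 80), 5)
  expect_lte(abs(ms$range[1] - 2 * A), 0.05)
  expect_equal(unname(ms$range[2:3]), c(0, 0))
  # too few observations: ranges only
  short <- make_track(xyz[1:5, , drop = FALSE])
  expect_true(is.na(motion_summary(short, fps = 25)$period_frames))
})

test_that("aperiodic smoothed-noise motion yields no significant period", {
  set.seed(31)
  path <- endorecon:::smoothed_noise_path(40, 1)
  ms <- motion_summary(make_track(cbind(path, 0, 0)), fps = 25)
  expect_true(is.na(ms$period_frames))
})

test_that("track CSV export round-trips exactly, blanks as empty fields", {
  xyz <- rbind(c(1.25, -2.5, 10), c(NA, NA, NA), c(1.3, -2.4, 10.1))
  tr <- make_track(xyz)
  f <- tempfile(fileext = ".csv")
  export_tracks(list(tr), f)
  lines <- readLines(f)
  expect_equal(length(lines), 4)  # header + 3 frames
  expect_match(lines[3], "^2,1,,,,blank$")
  back <- read_tracks(f)[[1]]
  expect_equal(back$xyz, tr$xyz, ignore_attr = TRUE)
  expect_equal(back$status, tr$status)
  expect_equal(back$frames, tr$frames)
})

test_that("a failed frame blanks only that entry and the mean fill restores it", {
  fx <- small_fixture()
  scene <- fx$scene; fit <- fx$fit
  cam <- scene$config$cam
  frames <- 9:14
  cats <- fit$categories$category[1]
  base <- track_categories(scene$left[frames], scene$right[frames], cats,
                           fit$model, cam)[[1]]
  expect_equal(length(base$frames), length(frames))
  expect_true(all(base$status == "observed"))
  # corrupt the middle frame: featureless left image -> category lost there
  left2 <- scene$left[frames]
  left2[[3]] <- matrix(0.2, nrow(left2[[3]]), ncol(left2[[3]]))
  broken <- track_categories(left2, scene$right[frames], cats,
                             fit$model, cam)[[1]]
  expect_equal(broken$status[3], "blank")
  expect_equal(broken$status[-3], base$status[-3])
  expect_equal(broken$xyz[-3, ], base$xyz[-3, ])  # later frames unaffected
  filled <- fill_gaps(broken)
  expect_equal(filled$status[3], "filled")
  expect_equal(filled$xyz[3, ], (broken$xyz[2, ] + broken$xyz[4, ]) / 2)
  expect_identical(fill_gaps(filled), filled)
})

test_that("static-scene tracks match the ground-truth 3D positions", {
  scene <- generate_scene(scene_config(n_markers = 12, n_frames = 6,
                                       lateral_amplitude = 0, depth_amplitude = 0,
                                       irregular_marker = FALSE, seed = 13))
  fit <- fit_matcher(scene$left[1:3], epochs = 25, learning_rate = 2e-3,
                     seed = 5, conv1 = 24, conv2 = 48, fc = 256)
  cam <- scene$config$cam
  tr <- track_categories(scene$left[4:6], scene$right[4:6],
                         fit$categories$category[1], fit$model, cam)[[1]]
  cmap <- category_marker_map(scene, fit$categories)
  mk <- cmap[as.character(fit$categories$category[1])]
  pos <- scene$truth$positions
  gt <- pos[pos$frame == 4 & pos$marker == mk, ]
  obs <- tr$xyz[tr$status == "observed", , drop = FALSE]
  expect_gt(nrow(obs), 0)
  err <- sqrt((obs[, 1] - gt$X)^2 + (obs[, 2] - gt$Y)^2 + (obs[, 3] - gt$Z)^2)
  # quantization bound: one pixel of disparity at d ~ 66 px, plus the
  # lateral offset of an integer-pixel detection
  expect_lt(max(err), 0.05 * gt$Z)
  expect_equal(length(tr$frames), 3)
})
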