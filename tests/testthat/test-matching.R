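test_that("match matrix keeps the per-category maximum with strict updates", {
  one <- data.frame(u = 10, v = 20, category = 3, probability = 0.8)
  mm <- build_match_matrix(one, 5)
  expect_equal(mm$probability, c(0, 0, 0.8, 0, 0))
  expect_equal(mm$position[3, ], c(u = 10, v = 20))
  expect_true(all(mm$position[-3, ] == 0))
  # strict ">" update: the later, higher-probability feature wins
  two <- data.frame(u = c(1, 2), v = c(1, 2), category = c(3, 3),
                    probability = c(0.6, 0.9))
  mm2 <- build_match_matrix(two, 5)
  expect_equal(mm2$position[3, ], c(u = 2, v = 2))
  # exact tie: the earliest-seen feature is retained
  tie <- data.frame(u = c(1, 2), v = c(1, 2), category = c(3, 3),
                    probability = c(0.7, 0.7))
  expect_equal(build_match_matrix(tie, 5)$position[3, ], c(u = 1, v = 1))
  expect_error(build_match_matrix(
    data.frame(u = 0, v = 0, category = 9, probability = 0.5), 5),
    "out of range")
})

test_that("match matrix equals the brute-force per-category argmax", {
  set.seed(10)
  for (rep in 1:20) {
    n <- 20
    k <- sample(5:200, 1)
    df <- data.frame(u = runif(k, 0, 100), v = runif(k, 0, 100),
                     category = sample(n, k, replace = TRUE),
                     probability = sample(seq(0, 1, by = 0.05), k,
                                          replace = TRUE))  # forces ties
    mm <- build_match_matrix(df, n)
    or <- oracle_match_matrix(df, n)
    expect_equal(unname(mm$probability), unname(or$probability))
    expect_equal(unname(mm$position), unname(or$position))
  }
})

test_that("matching intersects the nonzero categories of both matrices", {
  mk <- function(cats, n = 10) build_match_matrix(
    data.frame(u = cats, v = cats, category = cats,
               probability = rep(0.9, length(cats))), n)
  m <- compute_matches(mk(c(1, 4, 7)), mk(c(4, 7, 9)))
  expect_equal(m$category, c(4, 7))
  expect_equal(nrow(compute_matches(mk(integer(0)), mk(integer(0)))), 0)
  only_left <- compute_matches(mk(c(2)), mk(c(3)))
  expect_equal(nrow(only_left), 0)
  set.seed(11)
  for (rep in 1:10) {
    a <- sample(10, sample(0:10, 1)); b <- sample(10, sample(0:10, 1))
    m <- compute_matches(mk(a), mk(b))
    expect_lte(nrow(m), min(length(a), length(b)))
    expect_equal(m$category, sort(intersect(a, b)))
  }
})

test_that("category selection applies the persistence threshold", {
  fixed <- lapply(1:10, function(f) data.frame(u = 50, v = 50))
  cats <- select_categories(fixed, lambda = 1)
  expect_equal(nrow(cats), 1)
  expect_equal(cats$n_seen, 10)
  # a chain seen in 2 of 10 frames fails lambda = 0.3
  sparse <- c(lapply(1:2, function(f) data.frame(u = c(50, 10), v = c(50, 10))),
              lapply(3:10, function(f) data.frame(u = 50, v = 50)))
  cats2 <- select_categories(sparse, lambda = 0.3)
  expect_equal(nrow(cats2), 1)
  none <- lapply(1:10, function(f)
    data.frame(u = runif(1, 0, 1000), v = runif(1, 0, 1000)))
  expect_error(select_categories(none, lambda = 0.9), "empty category set")
})

test_that("a 52-marker synthetic scene yields exactly 52 categories at lambda 0.3", {
  scene <- generate_scene(scene_config(n_frames = 20, seed = 1))
  dets <- lapply(scene$left, detect_features)
  cats <- select_categories(dets, lambda = 0.3)
  expect_equal(nrow(cats), 52)
  # every category chain corresponds to one distinct ground-truth marker
  cmap <- category_marker_map(scene, cats)
  expect_false(any(duplicated(stats::na.omit(cmap))))
})

test_that("frame matching produces stereo-consistent pairs on the fixture", {
  fx <- small_fixture()
  m <- frame_matches(fx$scene$left[[12]], fx$scene$right[[12]], fx$fit$model)
  expect_gt(nrow(m), 0)
  counts <- attr(m, "counts")
  expect_lte(nrow(m), min(counts["detected_left"], counts["detected_right"]))
  # rectified pairs: vertical coordinates agree to a couple of pixels
  expect_lte(max(abs(m$lv - m$rv)), 2)
})
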