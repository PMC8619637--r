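cam_px <- stereo_camera(1, 0.99, c(100, 100), 0.001)

# four equal-depth markers as pixel match pairs with disparity d_px pixels
square_matches <- function(d_px = 50) {
  lu <- c(80, 120, 120, 80); lv <- c(80, 80, 120, 120)
  data.frame(category = 1:4, lu = lu, lv = lv, ru = lu - d_px, rv = lv)
}

test_that("equal-depth matches reconstruct a planar two-face mesh at Z = bf/d", {
  m <- square_matches(50)
  rec <- reconstruct_surface(m, cam_px, image_size = c(200, 200))
  expect_equal(nrow(rec$mesh$vertices), 4)
  expect_equal(nrow(rec$mesh$faces), 2)
  Z_expected <- 0.99 * 1 / (50 * 0.001)
  expect_equal(unname(rec$mesh$vertices[, 3]), rep(Z_expected, 4))
  expect_equal(rec$report$vertices, 4)
  expect_equal(rec$report$rejected_epipolar, 0)
})

test_that("matches failing the gates are dropped and counted", {
  m <- rbind(square_matches(50),
             data.frame(category = 5, lu = 60, lv = 60, ru = 110, rv = 60),
             data.frame(category = 6, lu = 60, lv = 90, ru = 20, rv = 140))
  rec <- reconstruct_surface(m, cam_px, image_size = c(200, 200))
  expect_equal(rec$report$pairs_in, 6)
  expect_equal(rec$report$rejected_epipolar, 1)
  expect_equal(rec$report$rejected_disparity, 1)
  expect_equal(rec$report$vertices, 4)
  expect_error(reconstruct_surface(square_matches()[1:2, ], cam_px,
                                   image_size = c(200, 200)),
               "insufficient")
})

test_that("translating both images vertically shifts Y by b*delta/d per point", {
  m <- square_matches(50)
  rec0 <- reconstruct_surface(m, cam_px, image_size = c(200, 200))
  delta_px <- 7
  m2 <- m; m2$lv <- m2$lv + delta_px; m2$rv <- m2$rv + delta_px
  rec1 <- reconstruct_surface(m2, cam_px, image_size = c(200, 200))
  d <- 50 * 0.001
  expect_equal(rec1$mesh$vertices[, 2] - rec0$mesh$vertices[, 2],
               rep(0.99 * delta_px * 0.001 / d, 4))
  expect_equal(rec1$mesh$vertices[, c(1, 3)], rec0$mesh$vertices[, c(1, 3)])
})

test_that("Laplacian smoothing fixes boundaries and preserves structure", {
  # 5-vertex pyramid: 4 boundary corners + 1 interior spike
  verts <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0), c(1, 1, 3))
  faces <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  uv <- cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  mesh <- surface_mesh(verts, faces, uv)
  expect_identical(laplacian_smooth(mesh, iterations = 0)$vertices, verts)
  expect_identical(laplacian_smooth(mesh, weight = 0)$vertices, verts)
  sm <- laplacian_smooth(mesh, iterations = 1, weight = 1)
  expect_equal(sm$vertices[5, ], colMeans(verts[1:4, ]))  # spike -> centroid
  expect_equal(sm$vertices[1:4, ], verts[1:4, ])          # boundary fixed
  expect_identical(sm$faces, mesh$faces)
  expect_identical(sm$uv, mesh$uv)
  # a planar mesh stays planar under any number of iterations
  flat <- surface_mesh(cbind(verts[, 1:2], 1), faces, uv)
  sflat <- laplacian_smooth(flat, iterations = 5, weight = 0.5)
  expect_equal(unname(sflat$vertices[, 3]), rep(1, 5))
})

test_that("mesh validation rejects malformed input", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(surface_mesh(verts, rbind(c(1, 2, 4)), cbind(0:2 / 2, 0)),
               "invalid vertex")
  expect_error(surface_mesh(verts, rbind(c(1, 2, 3)), cbind(c(0, 1), c(0, 1))),
               "one row per vertex")
  expect_error(surface_mesh(rbind(verts, c(2, 0, 0)),
                            rbind(c(1, 2, 4)), cbind(rep(0, 4), 0)),
               "zero-area")
})

test_that("PLY export round-trips bit-exactly and OBJ has the expected records", {
  m <- square_matches(50)
  rec <- reconstruct_surface(m, cam_px, image_size = c(200, 200))
  ply <- tempfile(fileext = ".ply")
  export_mesh(rec$mesh, ply, format = "ply")
  back <- import_mesh(ply)
  expect_identical(back$vertices, unname(rec$mesh$vertices))
  expect_identical(back$uv, unname(rec$mesh$uv))
  expect_identical(back$faces, rec$mesh$faces)
  # PLY stores 0-based face indices
  con <- file(ply, "rb"); hdr <- readLines(con, n = 2, warn = FALSE); close(con)
  expect_true(any(grepl("binary_little_endian", hdr)))

  obj <- tempfile(fileext = ".obj")
  export_mesh(rec$mesh, obj, format = "obj")
  lines <- readLines(obj)
  expect_equal(sum(grepl("^v ", lines)), 4)
  expect_equal(sum(grepl("^vt ", lines)), 4)
  expect_equal(sum(grepl("^f ", lines)), 2)
  # OBJ faces are 1-based vertex/uv references
  refs <- unlist(regmatches(lines, gregexpr("[0-9]+/[0-9]+", lines)))
  idx <- as.integer(sub("/.*", "", refs))
  expect_true(all(idx >= 1 & idx <= 4))
  back_obj <- import_mesh(obj)
  expect_equal(back_obj$vertices, unname(rec$mesh$vertices), tolerance = 1e-9)
})
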