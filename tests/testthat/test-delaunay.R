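test_that("orientation predicate distinguishes turns and collinearity", {
  expect_equal(orientation(c(0, 0), c(1, 0), c(0, 1)), "ccw")
  expect_equal(orientation(c(0, 0), c(0, 1), c(1, 0)), "cw")
  expect_equal(orientation(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("incircle predicate agrees with the explicit circumcircle", {
  A <- c(0, 0); B <- c(1, 0); C <- c(0, 1)
  expect_equal(in_circumcircle(A, B, C, c(0.9, 0.9)), "inside")
  expect_equal(in_circumcircle(A, B, C, c(10, 10)), "outside")
  expect_equal(in_circumcircle(A, B, C, c(1, 1)), "cocircular")
  expect_error(in_circumcircle(c(0, 0), c(1, 1), c(2, 2), c(0, 1)),
               "degenerate")
  set.seed(20)
  for (i in 1:50) {
    tr <- matrix(runif(6, -5, 5), 3, 2)
    if (orientation(tr[1, ], tr[2, ], tr[3, ]) == "collinear") next
    d <- runif(2, -6, 6)
    cc <- oracle_circumcircle(tr[1, ], tr[2, ], tr[3, ])
    dist <- sqrt(sum((d - cc$center)^2))
    got <- in_circumcircle(tr[1, ], tr[2, ], tr[3, ], d)
    if (abs(dist - cc$r) > 1e-6 * cc$r)
      expect_equal(got, ifelse(dist < cc$r, "inside", "outside"))
  }
})

test_that("the super triangle strictly contains every input point", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    pts <- cbind(runif(n, -50, 50), runif(n, -50, 50))
    st <- super_triangle(pts)
    for (j in seq_len(n)) {
      expect_equal(orientation(st[1, ], st[2, ], pts[j, ]), "ccw")
      expect_equal(orientation(st[2, ], st[3, ], pts[j, ]), "ccw")
      expect_equal(orientation(st[3, ], st[1, ], pts[j, ]), "ccw")
    }
  }
  # bounding-box-relative construction: translation equivariance
  pts <- cbind(runif(10), runif(10))
  st0 <- super_triangle(pts)
  st1 <- super_triangle(pts + 7)
  expect_equal(st1, st0 + 7)
})

test_that("cavity insertion splits a triangle and keeps the empty-circle property", {
  tri <- triangulation(rbind(c(0, 0), c(4, 0), c(0, 4)), rbind(1:3))
  out <- insert_point(tri, c(1, 1))
  expect_equal(nrow(out$triangles), 3)
  expect_true(all(out$triangles %in% 1:4))
  expect_true(is_delaunay(out))
  # +2 triangles per interior insertion; empty-circle holds throughout
  set.seed(22)
  pts <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  tri <- bowyer_watson(pts)
  inside <- c(5, 5)
  out2 <- insert_point(tri, inside)
  expect_equal(nrow(out2$triangles), nrow(tri$triangles) + 2)
  expect_equal(oracle_empty_circle_violations(out2$points, out2$triangles), 0)
  expect_error(insert_point(tri, pts[3, ]), "duplicate")
})

test_that("incremental triangulation handles minimal and degenerate inputs", {
  expect_equal(nrow(bowyer_watson(rbind(c(0, 0), c(1, 0), c(0, 1)))$triangles), 1)
  sq <- bowyer_watson(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(sq$triangles), 2)
  expect_equal(sum(!is.na(triangulation_edges(sq)$t2)), 1)  # one shared diagonal
  expect_error(bowyer_watson(rbind(c(0, 0), c(1, 0))), "at least 3")
  expect_error(bowyer_watson(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
               "collinear")
  expect_error(bowyer_watson(rbind(c(0, 0), c(1, 0), c(0, 1), c(0, 0))),
               "duplicate")
})

test_that("random point sets satisfy the empty-circle property and Euler counts", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    tri <- bowyer_watson(pts)
    validate_triangulation(tri)
    expect_equal(oracle_empty_circle_violations(pts, tri$triangles), 0)
    h <- length(chull(pts))
    expect_equal(nrow(tri$triangles), 2 * n - 2 - h)
    expect_equal(nrow(triangulation_edges(tri)), 3 * n - 3 - h)
  }
})

test_that("the triangle set is independent of insertion order in general position", {
  set.seed(24)
  for (i in 1:5) {
    n <- 12
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    if (has_cocircular_quad(pts)) next
    ref <- canon_tris(bowyer_watson(pts)$triangles)
    for (p in 1:4) {
      perm <- sample(n)
      tri <- bowyer_watson(pts[perm, ])
      # map permuted indices back to original labels before comparing
      remapped <- matrix(perm[tri$triangles], ncol = 3)
      expect_equal(canon_tris(remapped), ref)
    }
  }
})

test_that("LOP flips the diagonal when the opposite vertex invades the circumcircle", {
  # quad A, B, C, D triangulated as (B, C, D) + (B, D, A) with A inside the
  # circumcircle of BCD: one flip to the Delaunay diagonal is required
  pts <- rbind(A = c(0, 1), B = c(0, 0), C = c(1, 0), D = c(1.2, 1.2))
  bad <- triangulation(pts, rbind(c(2, 3, 4), c(2, 4, 1)))
  expect_equal(in_circumcircle(pts[2, ], pts[3, ], pts[4, ], pts[1, ]),
               "inside")
  fixed <- lop(bad)
  expect_equal(attr(fixed, "n_flips"), 1)
  expect_true(is_delaunay(fixed))
  # a Delaunay triangulation is a fixed point
  set.seed(25)
  pts2 <- cbind(runif(15), runif(15))
  tri <- bowyer_watson(pts2)
  again <- lop(tri)
  expect_equal(attr(again, "n_flips"), 0)
  expect_equal(canon_tris(again$triangles), canon_tris(tri$triangles))
})

test_that("LOP repairs flip-perturbed triangulations back to the Delaunay set", {
  set.seed(26)
  for (i in 1:6) {
    n <- sample(8:12, 1)
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    if (has_cocircular_quad(pts)) next
    ref <- bowyer_watson(pts)
    tris <- ref$triangles
    for (fl in 1:3) {  # wander away from Delaunay with random valid flips
      edges <- internal_edges_of(tris)
      if (!length(edges)) break
      for (ab in sample(edges)) {
        nt <- oracle_flip(pts, tris, ab)
        if (!is.null(nt)) { tris <- nt; break }
      }
    }
    repaired <- lop(triangulation(pts, tris))
    expect_equal(canon_tris(repaired$triangles), canon_tris(ref$triangles))
  }
})

test_that("output minimum angle is maximal over all enumerated triangulations", {
  set.seed(27)
  done <- 0
  while (done < 5) {
    n <- sample(6:8, 1)
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    if (has_cocircular_quad(pts)) next
    tri <- bowyer_watson(pts)
    all_tris <- enumerate_triangulations(pts, tri$triangles)
    best <- min_triangle_angle(tri)
    for (alt in all_tris)
      expect_gte(best + 1e-12, oracle_min_angle(pts, alt))
    done <- done + 1
  }
})

test_that("plane projection lifts the 2D connectivity unchanged to 3D", {
  cam <- stereo_camera(1, 0.99, c(0, 0), 0.01)
  set.seed(28)
  # points at uniform depth: projection is a similarity, mesh is planar
  P <- cbind(runif(12, -2, 2), runif(12, -2, 2), 5)
  st <- plane_project_triangulate(P, cam)
  tri2 <- lop(bowyer_watson(st$points2d))
  expect_equal(canon_tris(st$triangles), canon_tris(tri2$triangles))
  expect_error(plane_project_triangulate(cbind(0, 0, -1), cam), "invalid depth")
})

test_that("OFF-style text export round-trips points and faces", {
  set.seed(29)
  tri <- bowyer_watson(cbind(runif(10), runif(10)))
  f <- tempfile(fileext = ".off")
  write_triangulation(tri, f)
  back <- read_triangulation(f)
  expect_equal(back$points, tri$points)
  expect_equal(canon_tris(back$triangles), canon_tris(tri$triangles))
})
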