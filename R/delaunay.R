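# From-scratch 2D Delaunay triangulation by incremental (Bowyer-Watson)
# cavity insertion, with Lawson's local optimization procedure (LOP)
# available as a separate repair pass, and plane-projection triangulation of
# 3D point clouds. Predicates use floating point with relative tolerance
# bands rather than exact arithmetic: input coordinates are image-scale and
# well conditioned, which keeps the simple predicates reliable.

#' Orientation of an ordered point triple
#'
#' Sign of the signed doubled triangle area; magnitudes below a relative
#' tolerance report `"collinear"`.
#'
#' @param a,b,c length-2 numeric vectors.
#' @param eps absolute tolerance on the doubled area, scaled internally by
#'   the squared coordinate magnitude.
#' @return One of `"ccw"`, `"cw"`, `"collinear"`.
#' @export
orientation <- function(a, b, c, eps = 1e-12) {
  cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  s <- max(1, abs(a[1]), abs(a[2]), abs(b[1]), abs(b[2]), abs(c[1]), abs(c[2]))
  if (abs(cr) <= eps * s^2) "collinear" else if (cr > 0) "ccw" else "cw"
}

# Circumcircle of a non-degenerate triangle: centre and squared radius.
circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (d == 0) stop("degenerate triangle: collinear vertices")
  a2 <- a[1]^2 + a[2]^2; b2 <- b[1]^2 + b[2]^2; c2 <- c[1]^2 + c[2]^2
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(center = c(ux, uy), r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Empty-circumcircle predicate
#'
#' Tests whether `d` lies inside the circumcircle of the counter-clockwise
#' triangle `a, b, c`, using the standard incircle determinant with a
#' relative tolerance band for the cocircular case.
#'
#' @param a,b,c triangle vertices in counter-clockwise order (a clockwise
#'   triple is reoriented internally; collinear is an error).
#' @param d query point.
#' @param eps relative tolerance of the cocircular band.
#' @return One of `"inside"`, `"outside"`, `"cocircular"`.
#' @export
in_circumcircle <- function(a, b, c, d, eps = 1e-12) {
  o <- orientation(a, b, c)
  if (o == "collinear") stop("degenerate triangle: collinear vertices")
  if (o == "cw") { tmp <- b; b <- c; c <- tmp }
  ax <- a[1] - d[1]; ay <- a[2] - d[2]
  bx <- b[1] - d[1]; by <- b[2] - d[2]
  cx <- c[1] - d[1]; cy <- c[2] - d[2]
  det <- (ax^2 + ay^2) * (bx * cy - by * cx) -
         (bx^2 + by^2) * (ax * cy - ay * cx) +
         (cx^2 + cy^2) * (ax * by - ay * bx)
  s <- max(1, abs(ax), abs(ay), abs(bx), abs(by), abs(cx), abs(cy))
  if (abs(det) <= eps * s^4) "cocircular" else if (det > 0) "inside" else "outside"
}

#' Bootstrap super triangle enclosing a point set
#'
#' Returns three synthetic vertices of an equilateral-ish triangle centred
#' on the bounding box, sized `margin_factor` times the box diagonal, so
#' every input point is strictly inside. The construction is relative to the
#' bounding box, hence translation-equivariant.
#'
#' @param points `n x 2` matrix.
#' @param margin_factor size multiplier on the bounding-box diagonal.
#' @return A `3 x 2` matrix of counter-clockwise vertices.
#' @export
super_triangle <- function(points, margin_factor = 10) {
  pts <- as_point_matrix(points, 2)$m
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  diag <- sqrt(diff(range(pts[, 1]))^2 + diff(range(pts[, 2]))^2)
  r <- max(diag, 1) * margin_factor
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  cbind(cx + 2 * r * cos(ang), cy + 2 * r * sin(ang))
}

# --- internal incremental state ------------------------------------------
# Real points have positive indices into `points`; the three synthetic
# super-triangle vertices carry negative indices -1, -2, -3 so their removal
# at the end is unambiguous.

bw_pt <- function(state, i) {
  if (i > 0) state$points[i, ] else state$super[-i, ]
}

bw_add_triangle <- function(state, v) {
  a <- bw_pt(state, v[1]); b <- bw_pt(state, v[2]); c <- bw_pt(state, v[3])
  if (orientation(a, b, c) == "cw") { v <- v[c(1, 3, 2)]; tmp <- b; b <- c; c <- tmp }
  if (any(v < 0)) {
    # synthetic (super) vertex: the circumcircle is handled symbolically
    cc <- list(center = c(NA_real_, NA_real_), r2 = NA_real_)
  } else {
    cc <- circumcircle(a, b, c)
  }
  state$tris <- rbind(state$tris, v)
  state$ccx <- c(state$ccx, cc$center[1])
  state$ccy <- c(state$ccy, cc$center[2])
  state$r2 <- c(state$r2, cc$r2)
  state
}

# Circumcircle membership for a triangle holding super-triangle vertices,
# with those vertices taken to infinity along their fixed directions (the
# exact limit of the incircle determinant). This keeps the convex hull
# complete even when near-collinear hull triples have enormous circumcircles
# that any finite super triangle would fail to contain.
bw_super_in_circle <- function(state, row, p) {
  v <- state$tris[row, ]
  sup <- v < 0
  ns <- sum(sup)
  if (ns == 3L) return(TRUE)  # initial super triangle covers everything
  if (ns == 1L) {
    # cyclic rotation putting the super vertex last: (a, b, s) stays ccw;
    # the limit circle is the open half-plane left of the directed edge ab
    k <- which(sup)
    ord <- ((k + 0:2) %% 3L) + 1L  # (k+1, k+2, k) in cyclic order
    a <- bw_pt(state, v[ord[1]])
    b <- bw_pt(state, v[ord[2]])
    return(orientation(a, b, p) == "ccw")
  }
  # two super vertices: rotate so the finite vertex comes first (f, s1, s2);
  # membership reduces to a half-plane through f set by the two directions
  k <- which(!sup)
  ord <- ((k - 1 + 0:2) %% 3L) + 1L
  f <- bw_pt(state, v[ord[1]])
  d1 <- state$super_dirs[-v[ord[2]], ]
  d2 <- state$super_dirs[-v[ord[3]], ]
  cr <- (f[1] - p[1]) * (d1[2] - d2[2]) - (f[2] - p[2]) * (d1[1] - d2[1])
  s <- max(1, abs(f[1]), abs(f[2]), abs(p[1]), abs(p[2]))
  cr > 1e-12 * s
}

# Insert the point with index pidx (coordinates p) by cavity retriangulation:
# delete every triangle whose circumcircle strictly contains p and connect p
# to the cavity boundary. Cocircular points count as outside, so insertion
# order decides the diagonal of cocircular quadruples.
bw_cavity_insert <- function(state, pidx, p) {
  d2 <- (p[1] - state$ccx)^2 + (p[2] - state$ccy)^2
  bad <- which(!is.na(state$r2) & d2 < state$r2 * (1 - 1e-12))
  sup_rows <- which(is.na(state$r2))
  if (length(sup_rows))
    bad <- c(bad, sup_rows[vapply(sup_rows, function(r)
      bw_super_in_circle(state, r, p), logical(1))])
  if (length(bad) == 0)
    stop("point (", p[1], ", ", p[2], ") lies outside the triangulation cover")
  # directed edges of the bad triangles; boundary = undirected singletons
  e <- rbind(state$tris[bad, c(1, 2), drop = FALSE],
             state$tris[bad, c(2, 3), drop = FALSE],
             state$tris[bad, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  boundary <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  state$tris <- state$tris[-bad, , drop = FALSE]
  state$ccx <- state$ccx[-bad]; state$ccy <- state$ccy[-bad]
  state$r2 <- state$r2[-bad]
  for (r in seq_len(nrow(boundary)))
    state <- bw_add_triangle(state, c(boundary[r, ], pidx))
  state
}

#' Construct a triangulation object
#'
#' Normalizes every triangle to counter-clockwise orientation and performs
#' basic integrity checks (valid indices, no degenerate or duplicate
#' triangles).
#'
#' @param points `n x 2` coordinate matrix.
#' @param triangles `T x 3` matrix of 1-based vertex indices.
#' @return An object of class `triangulation` with elements `points` and
#'   `triangles`.
#' @export
triangulation <- function(points, triangles) {
  pts <- as_point_matrix(points, 2)$m
  dimnames(pts) <- NULL
  tris <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(all(tris >= 1), all(tris <= nrow(pts)))
  for (r in seq_len(nrow(tris))) {
    o <- orientation(pts[tris[r, 1], ], pts[tris[r, 2], ], pts[tris[r, 3], ])
    if (o == "collinear") stop("degenerate (collinear) triangle in row ", r)
    if (o == "cw") tris[r, ] <- tris[r, c(1, 3, 2)]
  }
  key <- apply(tris, 1, function(v) paste(sort(v), collapse = "-"))
  if (anyDuplicated(key)) stop("duplicate triangle")
  structure(list(points = pts, triangles = tris), class = "triangulation")
}

#' @export
print.triangulation <- function(x, ...) {
  cat(sprintf("<triangulation> %d points, %d triangles\n",
              nrow(x$points), nrow(x$triangles)))
  invisible(x)
}

# Undirected edge table: one row per unique edge with the indices of its
# incident triangles (t2 = NA for hull edges).
edge_table <- function(tris) {
  e <- rbind(tris[, c(1, 2), drop = FALSE], tris[, c(2, 3), drop = FALSE],
             tris[, c(3, 1), drop = FALSE])
  tid <- rep(seq_len(nrow(tris)), 3)
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  first <- !duplicated(key)
  map <- match(key, key[first])
  n_e <- sum(first)
  t1 <- rep(NA_integer_, n_e); t2 <- rep(NA_integer_, n_e)
  for (i in seq_along(key)) {
    j <- map[i]
    if (is.na(t1[j])) t1[j] <- tid[i]
    else if (is.na(t2[j])) t2[j] <- tid[i]
    else stop("edge shared by more than two triangles")
  }
  data.frame(a = a[first], b = b[first], t1 = t1, t2 = t2)
}

#' Edges of a triangulation
#'
#' @param tri a `triangulation`.
#' @return Data frame with vertex columns `a < b` and incident triangle rows
#'   `t1`, `t2` (`t2` is `NA` on hull edges).
#' @export
triangulation_edges <- function(tri) {
  stopifnot(inherits(tri, "triangulation"))
  edge_table(tri$triangles)
}

#' Incremental Delaunay triangulation (Bowyer-Watson)
#'
#' Inserts the points one by one into an enclosing super triangle: all
#' triangles whose circumcircle contains the new point are deleted and the
#' cavity is retriangulated from its boundary. Super-triangle vertices (held
#' at negative indices during construction) and their incident triangles are
#' removed at the end, leaving the Delaunay triangulation of the convex
#' hull. For cocircular quadruples the insertion order decides the diagonal.
#'
#' @param points `n x 2` matrix, `n >= 3`, no duplicates, not all collinear.
#' @param margin_factor super-triangle size factor, see [super_triangle()].
#' @param eps_dup duplicate-point rejection distance.
#' @return A [triangulation()].
#' @export
bowyer_watson <- function(points, margin_factor = 10, eps_dup = 1e-9) {
  pts <- as_point_matrix(points, 2)$m
  n <- nrow(pts)
  if (n < 3) stop("degenerate input: need at least 3 points")
  if (n <= 2048) {
    dd <- as.matrix(stats::dist(pts))
    diag(dd) <- Inf
    if (any(dd < eps_dup)) stop("duplicate point (within eps_dup)")
  }
  j <- which(pts[, 1] != pts[1, 1] | pts[, 2] != pts[1, 2])[1]
  non_col <- FALSE
  for (k in seq_len(n)) {
    if (k != 1 && k != j &&
        orientation(pts[1, ], pts[j, ], pts[k, ]) != "collinear") {
      non_col <- TRUE; break
    }
  }
  if (!non_col) stop("degenerate input: all points are collinear")

  super <- super_triangle(pts, margin_factor)
  ctr <- colMeans(super)
  dirs <- sweep(super, 2, ctr)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  state <- list(points = pts, super = super, super_dirs = dirs,
                tris = matrix(integer(0), 0, 3),
                ccx = numeric(0), ccy = numeric(0), r2 = numeric(0))
  state <- bw_add_triangle(state, c(-1L, -2L, -3L))
  for (i in seq_len(n)) state <- bw_cavity_insert(state, i, pts[i, ])
  keep <- apply(state$tris > 0, 1, all)
  triangulation(pts, state$tris[keep, , drop = FALSE])
}

#' Insert one point into an existing triangulation
#'
#' Cavity (Bowyer-Watson) insertion of a point lying inside the cover of
#' the current triangulation: the influence triangles (those whose
#' circumcircle contains the point) are removed and the cavity is
#' retriangulated around the new vertex, restoring the local Delaunay
#' property.
#'
#' @param tri a `triangulation`.
#' @param p length-2 point inside the triangulated region.
#' @param eps_dup duplicate-point rejection distance.
#' @return The updated `triangulation`; the new point is appended as the
#'   last vertex.
#' @export
insert_point <- function(tri, p, eps_dup = 1e-9) {
  stopifnot(inherits(tri, "triangulation"), length(p) == 2)
  pts <- tri$points
  if (any((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 < eps_dup^2))
    stop("duplicate point (within eps_dup)")
  state <- list(points = rbind(pts, p), super = NULL,
                tris = matrix(integer(0), 0, 3),
                ccx = numeric(0), ccy = numeric(0), r2 = numeric(0))
  for (r in seq_len(nrow(tri$triangles)))
    state <- bw_add_triangle(state, tri$triangles[r, ])
  state <- bw_cavity_insert(state, nrow(pts) + 1L, as.numeric(p))
  triangulation(state$points, state$tris)
}

#' Lawson local optimization procedure (LOP)
#'
#' Repeatedly examines adjacent triangle pairs: when the vertex opposite the
#' shared edge lies inside the circumcircle of the neighbouring triangle,
#' the shared diagonal is swapped. Pairs whose quadrilateral is not strictly
#' convex are skipped (a flip would invert orientation). Terminates when no
#' flippable edge remains; a Delaunay input is returned unchanged.
#'
#' @param tri a `triangulation`.
#' @return The optimized `triangulation` with attribute `"n_flips"`.
#' @export
lop <- function(tri) {
  stopifnot(inherits(tri, "triangulation"))
  pts <- tri$points
  tris <- tri$triangles
  n_flips <- 0L
  repeat {
    et <- edge_table(tris)
    flipped <- FALSE
    for (r in which(!is.na(et$t2))) {
      a <- et$a[r]; b <- et$b[r]
      t1 <- et$t1[r]; t2 <- et$t2[r]
      c1 <- setdiff(tris[t1, ], c(a, b))
      c2 <- setdiff(tris[t2, ], c(a, b))
      pa <- pts[a, ]; pb <- pts[b, ]; pc <- pts[c1, ]; pd <- pts[c2, ]
      # strict convexity of quad: ab and cd must properly cross
      if (orientation(pc, pd, pa) == "collinear" ||
          orientation(pc, pd, pb) == "collinear" ||
          orientation(pc, pd, pa) == orientation(pc, pd, pb)) next
      if (in_circumcircle(pa, pb, pc, pd) != "inside") next
      tris[t1, ] <- c(a, c1, c2)
      tris[t2, ] <- c(b, c1, c2)
      for (tt in c(t1, t2)) {
        v <- tris[tt, ]
        if (orientation(pts[v[1], ], pts[v[2], ], pts[v[3], ]) == "cw")
          tris[tt, ] <- v[c(1, 3, 2)]
      }
      n_flips <- n_flips + 1L
      flipped <- TRUE
      break
    }
    if (!flipped) break
  }
  out <- triangulation(pts, tris)
  attr(out, "n_flips") <- n_flips
  out
}

#' Verify triangulation invariants
#'
#' Checks counter-clockwise orientation, edge incidence (internal edges in
#' exactly two triangles, hull edges in one, hull = convex hull of the
#' points) and optionally the Delaunay empty-circle property by brute force.
#'
#' @param tri a `triangulation`.
#' @param delaunay also check the empty-circumcircle property.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_triangulation <- function(tri, delaunay = FALSE) {
  stopifnot(inherits(tri, "triangulation"))
  pts <- tri$points; tris <- tri$triangles
  for (r in seq_len(nrow(tris)))
    if (orientation(pts[tris[r, 1], ], pts[tris[r, 2], ], pts[tris[r, 3], ]) != "ccw")
      stop("triangle ", r, " is not counter-clockwise")
  et <- edge_table(tris)  # errors if an edge has > 2 incident triangles
  boundary <- et[is.na(et$t2), ]
  bv <- table(c(boundary$a, boundary$b))
  if (any(bv != 2))
    stop("boundary edges do not form a closed cycle")
  if (!all(chull(pts) %in% as.integer(names(bv))))
    stop("a convex-hull vertex is not on the boundary")
  if (delaunay && !is_delaunay(tri))
    stop("empty-circumcircle property violated")
  invisible(TRUE)
}

#' Brute-force empty-circle check
#'
#' Scans every vertex against every triangle's circumcircle (computed from
#' the explicit circumcentre); strict containment of a non-vertex point is a
#' violation.
#'
#' @param tri a `triangulation`.
#' @param eps relative slack excluding cocircular points.
#' @return `TRUE` when no strict violation exists.
#' @export
is_delaunay <- function(tri, eps = 1e-9) {
  pts <- tri$points; tris <- tri$triangles
  for (r in seq_len(nrow(tris))) {
    cc <- circumcircle(pts[tris[r, 1], ], pts[tris[r, 2], ], pts[tris[r, 3], ])
    d2 <- (pts[, 1] - cc$center[1])^2 + (pts[, 2] - cc$center[2])^2
    inside <- which(d2 < cc$r2 * (1 - eps))
    if (length(setdiff(inside, tris[r, ])) > 0) return(FALSE)
  }
  TRUE
}

#' Minimum interior angle of a triangulation
#'
#' @param tri a `triangulation`.
#' @return The smallest interior angle (radians) over all triangles.
#' @export
min_triangle_angle <- function(tri) {
  pts <- tri$points
  ang <- function(p, q, r) {  # angle at p
    v1 <- q - p; v2 <- r - p
    acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }
  m <- Inf
  for (r in seq_len(nrow(tri$triangles))) {
    v <- tri$triangles[r, ]
    a <- pts[v[1], ]; b <- pts[v[2], ]; c <- pts[v[3], ]
    m <- min(m, ang(a, b, c), ang(b, c, a), ang(c, a, b))
  }
  m
}

#' Triangulate a 3D point cloud by plane projection
#'
#' Projects the 3D points onto the left imaging plane through the rectified
#' camera model, triangulates the 2D projections (Bowyer-Watson, then an LOP
#' verification pass) and lifts the connectivity unchanged to 3D.
#'
#' @param points3d `n x 3` matrix in the left camera frame, all `Z > 0`.
#' @param cam a [stereo_camera()].
#' @return An object of class `surface_triangulation` with elements
#'   `points3d`, `triangles` (identical index set to the planar
#'   triangulation) and `points2d` (the projections, camera-plane units).
#' @export
plane_project_triangulate <- function(points3d, cam) {
  pts3 <- as_point_matrix(points3d, 3)$m
  if (any(pts3[, 3] <= 0)) stop("invalid depth: all Z must be > 0")
  proj <- project_point(pts3, cam)
  tri2 <- lop(bowyer_watson(proj$left))
  structure(list(points3d = pts3, triangles = tri2$triangles,
                 points2d = proj$left),
            class = "surface_triangulation")
}

#' @export
print.surface_triangulation <- function(x, ...) {
  cat(sprintf("<surface_triangulation> %d points, %d triangles\n",
              nrow(x$points3d), nrow(x$triangles)))
  invisible(x)
}

#' Write / read a triangulation as OFF-style text
#'
#' Plain-text fixture format: an `OFF` header line, a count line
#' `n_vertices n_faces`, one vertex line per point and one face line
#' `3 i j k` per triangle with 0-based indices.
#'
#' @param tri a `triangulation`.
#' @param path output file.
#' @return `write_triangulation()` returns `path` invisibly;
#'   `read_triangulation()` the reconstructed `triangulation`.
#' @export
write_triangulation <- function(tri, path) {
  stopifnot(inherits(tri, "triangulation"))
  lines <- c("OFF",
             paste(nrow(tri$points), nrow(tri$triangles)),
             apply(tri$points, 1, function(p) paste(sprintf("%.17g", p), collapse = " ")),
             apply(tri$triangles, 1, function(v) paste(c(3, v - 1L), collapse = " ")))
  atomic_write(path, function(tmp) writeLines(lines, tmp))
  invisible(path)
}

#' @rdname write_triangulation
#' @export
read_triangulation <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vs <- t(vapply(lines[3:(2 + nv)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                 numeric(2)))
  fs <- t(vapply(lines[(3 + nv):(2 + nv + nf)],
                 function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]])[2:4] + 1L,
                 integer(3)))
  triangulation(vs, fs)
}
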