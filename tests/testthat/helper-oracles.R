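# Independent oracles used by the geometry and matching tests. These are
# deliberately written from first principles (linear solves, exhaustive
# search, flip-graph enumeration) and share no code with the package
# implementations they check.

# Circumcentre by solving the two perpendicular-bisector equations.
oracle_circumcircle <- function(a, b, c) {
  A <- rbind(2 * (b - a), 2 * (c - a))
  rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2))
  ctr <- solve(A, rhs)
  list(center = ctr, r = sqrt(sum((a - ctr)^2)))
}

# Brute-force empty-circle scan: every vertex against every triangle's
# circumcircle; strict containment of a non-vertex is a violation.
oracle_empty_circle_violations <- function(pts, tris, eps = 1e-9) {
  bad <- 0L
  for (r in seq_len(nrow(tris))) {
    cc <- oracle_circumcircle(pts[tris[r, 1], ], pts[tris[r, 2], ],
                              pts[tris[r, 3], ])
    d <- sqrt((pts[, 1] - cc$center[1])^2 + (pts[, 2] - cc$center[2])^2)
    inside <- which(d < cc$r * (1 - eps))
    bad <- bad + length(setdiff(inside, tris[r, ]))
  }
  bad
}

oracle_orient <- function(a, b, c) {
  sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
}

oracle_min_angle <- function(pts, tris) {
  ang <- function(p, q, r) {
    v1 <- q - p; v2 <- r - p
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }
  m <- Inf
  for (r in seq_len(nrow(tris))) {
    a <- pts[tris[r, 1], ]; b <- pts[tris[r, 2], ]; c <- pts[tris[r, 3], ]
    m <- min(m, ang(a, b, c), ang(b, c, a), ang(c, a, b))
  }
  m
}

canon_tris <- function(tris) {
  paste(sort(apply(tris, 1, function(v) paste(sort(v), collapse = "-"))),
        collapse = ";")
}

# One diagonal flip of the internal edge (ab) shared by two triangles, or
# NULL when the surrounding quadrilateral is not strictly convex.
oracle_flip <- function(pts, tris, ab) {
  rows <- which(apply(tris, 1, function(t) all(ab %in% t)))
  if (length(rows) != 2) return(NULL)
  c1 <- setdiff(tris[rows[1], ], ab)
  c2 <- setdiff(tris[rows[2], ], ab)
  p <- pts[c1, ]; q <- pts[c2, ]
  a <- pts[ab[1], ]; b <- pts[ab[2], ]
  if (oracle_orient(p, q, a) * oracle_orient(p, q, b) >= 0) return(NULL)
  if (oracle_orient(a, b, p) * oracle_orient(a, b, q) >= 0) return(NULL)
  tris[rows[1], ] <- c(ab[1], c1, c2)
  tris[rows[2], ] <- c(ab[2], c1, c2)
  tris
}

internal_edges_of <- function(tris) {
  e <- rbind(tris[, 1:2, drop = FALSE], tris[, 2:3, drop = FALSE],
             tris[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  lapply(names(tab)[tab == 2], function(k)
    as.integer(strsplit(k, " ")[[1]]))
}

# Exhaustive enumeration of all triangulations of a planar point set by
# breadth-first traversal of the (connected) flip graph.
enumerate_triangulations <- function(pts, start_tris) {
  seen <- new.env(parent = emptyenv())
  assign(canon_tris(start_tris), start_tris, envir = seen)
  queue <- list(start_tris)
  while (length(queue)) {
    tris <- queue[[1]]; queue <- queue[-1]
    for (ab in internal_edges_of(tris)) {
      nt <- oracle_flip(pts, tris, ab)
      if (is.null(nt)) next
      ck <- canon_tris(nt)
      if (!exists(ck, envir = seen)) {
        assign(ck, nt, envir = seen)
        queue <- c(queue, list(nt))
      }
    }
  }
  mget(ls(seen), envir = seen)
}

# Brute-force per-category argmax with the strict-inequality tie rule
# (earliest-seen feature wins exact ties).
oracle_match_matrix <- function(df, n) {
  pos <- matrix(0, n, 2)
  prob <- numeric(n)
  for (cc in seq_len(n)) {
    rows <- which(df$category == cc)
    if (!length(rows)) next
    best <- rows[which.max(df$probability[rows])]  # first max
    if (df$probability[best] <= 0) next  # strict ">" never accepts zero
    pos[cc, ] <- c(df$u[best], df$v[best])
    prob[cc] <- df$probability[best]
  }
  list(position = pos, probability = prob)
}

# Does a point set contain four cocircular points? (used to exempt
# cocircular ties from uniqueness/optimality checks)
has_cocircular_quad <- function(pts, tol = 1e-7) {
  n <- nrow(pts)
  cmb <- utils::combn(n, 3)
  for (j in seq_len(ncol(cmb))) {
    tri <- cmb[, j]
    if (oracle_orient(pts[tri[1], ], pts[tri[2], ], pts[tri[3], ]) == 0)
      next
    cc <- oracle_circumcircle(pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])
    d <- sqrt((pts[, 1] - cc$center[1])^2 + (pts[, 2] - cc$center[2])^2)
    others <- setdiff(seq_len(n), tri)
    if (any(abs(d[others] - cc$r) < tol * max(1, cc$r))) return(TRUE)
  }
  FALSE
}
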