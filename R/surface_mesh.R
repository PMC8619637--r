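# Textured surface mesh assembly from matched stereo features, optional
# Laplacian joint smoothing, and OBJ/PLY writers.

#' Construct a textured surface mesh
#'
#' @param vertices `V x 3` matrix of 3D positions (left camera frame).
#' @param faces `F x 3` matrix of 1-based vertex indices.
#' @param uv `V x 2` matrix of texture coordinates in `[0, 1]^2` referencing
#'   the left image (OBJ convention: origin bottom-left).
#' @param texture optional grayscale left-image matrix used as the texture.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, uv, texture = NULL) {
  vertices <- as_point_matrix(vertices, 3)$m
  uv <- as_point_matrix(uv, 2)$m
  dimnames(vertices) <- NULL
  dimnames(uv) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(uv) != nrow(vertices)) stop("uv must have one row per vertex")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face references an invalid vertex")
  for (r in seq_len(nrow(faces))) {
    v <- vertices[faces[r, ], , drop = FALSE]
    n <- crossprod_3d(v[2, ] - v[1, ], v[3, ] - v[1, ])
    if (sum(n^2) == 0) stop("zero-area face in row ", r)
  }
  structure(list(vertices = vertices, faces = faces, uv = uv,
                 texture = texture),
            class = "surface_mesh")
}

crossprod_3d <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$texture)) "" else ", textured"))
  invisible(x)
}

#' Reconstruct a textured 3D surface from stereo matches
#'
#' Match pairs (pixel coordinates) are gated — rectified epipolar tolerance
#' and positive disparity — recovered to 3D through the camera model,
#' triangulated by plane projection onto the left imaging plane, and
#' textured with per-vertex UV coordinates taken from the left pixel
#' position. Pairs failing a gate are dropped and counted in the report.
#'
#' @param matches data frame with 0-based pixel columns `lu`, `lv`, `ru`,
#'   `rv` (as produced by [frame_matches()]).
#' @param cam a [stereo_camera()].
#' @param image_size `(width, height)` of the frames in pixels (used for UV
#'   normalization).
#' @param left_image optional left frame matrix stored as the mesh texture.
#' @return A list with elements `mesh` (a [surface_mesh()]) and `report`
#'   (counts: input pairs, epipolar rejections, disparity rejections,
#'   vertices, faces).
#' @export
reconstruct_surface <- function(matches, cam, image_size, left_image = NULL) {
  stopifnot(is.data.frame(matches), inherits(cam, "stereo_camera"),
            length(image_size) == 2)
  n_in <- nrow(matches)
  l <- pixel_to_camera(cbind(matches$lu, matches$lv), cam)
  r <- pixel_to_camera(cbind(matches$ru, matches$rv), cam)
  pair_all <- image_point_pair(l, r)
  ok_epi <- epipolar_gate(pair_all, cam)
  ok_disp <- disparity(pair_all) > 0
  usable <- ok_epi & ok_disp
  if (sum(usable) < 3)
    stop("insufficient points: need >= 3 usable matches, got ", sum(usable))
  pair <- image_point_pair(l[usable, , drop = FALSE], r[usable, , drop = FALSE])
  P <- recover_point3d(pair, cam)
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  st <- plane_project_triangulate(P, cam)
  W <- image_size[1]; H <- image_size[2]
  uv <- cbind((matches$lu[usable] + 0.5) / W,
              1 - (matches$lv[usable] + 0.5) / H)
  mesh <- surface_mesh(P, st$triangles, uv, texture = left_image)
  list(mesh = mesh,
       report = list(pairs_in = n_in,
                     rejected_epipolar = sum(!ok_epi),
                     rejected_disparity = sum(ok_epi & !ok_disp),
                     vertices = nrow(mesh$vertices),
                     faces = nrow(mesh$faces)))
}

mesh_boundary_vertices <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(integer(0))
  et <- edge_table(mesh$faces)
  hull <- et[is.na(et$t2), ]
  unique(c(hull$a, hull$b))
}

#' Smooth triangle joints by Laplacian averaging
#'
#' Each interior vertex is moved toward the centroid of its edge-connected
#' neighbours by fraction `weight` per iteration (Jacobi update). Boundary
#' vertices never move; UV coordinates and connectivity are unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of smoothing passes.
#' @param weight step fraction toward the neighbour centroid, in `[0, 1]`.
#' @return The smoothed `surface_mesh`.
#' @export
laplacian_smooth <- function(mesh, iterations = 2, weight = 0.5) {
  stopifnot(inherits(mesh, "surface_mesh"), weight >= 0, weight <= 1)
  if (iterations == 0 || weight == 0 || nrow(mesh$faces) == 0) return(mesh)
  et <- edge_table(mesh$faces)
  fixed <- mesh_boundary_vertices(mesh)
  nv <- nrow(mesh$vertices)
  nbr <- vector("list", nv)
  for (r in seq_len(nrow(et))) {
    nbr[[et$a[r]]] <- c(nbr[[et$a[r]]], et$b[r])
    nbr[[et$b[r]]] <- c(nbr[[et$b[r]]], et$a[r])
  }
  V <- mesh$vertices
  movable <- setdiff(which(lengths(nbr) > 0), fixed)
  for (it in seq_len(iterations)) {
    Vnew <- V
    for (i in movable) {
      cen <- colMeans(V[nbr[[i]], , drop = FALSE])
      Vnew[i, ] <- (1 - weight) * V[i, ] + weight * cen
    }
    V <- Vnew
  }
  mesh$vertices <- V
  mesh
}

#' Export a surface mesh to OBJ or PLY
#'
#' OBJ output is text (`v`, `vt`, `f` records, faces referencing
#' vertex/uv with 1-based indices) with an accompanying `.mtl` material and
#' PNG texture when the mesh carries one. PLY output is
#' binary-little-endian with double-precision `x, y, z, u, v` vertex
#' properties (0-based face indices), so a re-import round-trips
#' bit-exactly.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"obj"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = c("obj", "ply")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- match.arg(format)
  if (format == "obj") export_obj(mesh, path) else export_ply(mesh, path)
  invisible(path)
}

export_obj <- function(mesh, path) {
  base <- sub("\\.obj$", "", basename(path))
  lines <- character(0)
  if (!is.null(mesh$texture)) {
    mtl_path <- file.path(dirname(path), paste0(base, ".mtl"))
    tex_path <- file.path(dirname(path), paste0(base, ".png"))
    write_frame(mesh$texture, tex_path)
    atomic_write(mtl_path, function(tmp) writeLines(c(
      "newmtl material0", "Ka 1 1 1", "Kd 1 1 1",
      paste0("map_Kd ", basename(tex_path))), tmp))
    lines <- c(lines, paste0("mtllib ", basename(mtl_path)))
  }
  lines <- c(lines,
             apply(mesh$vertices, 1, function(p)
               paste("v", paste(sprintf("%.10g", p), collapse = " "))),
             apply(mesh$uv, 1, function(p)
               paste("vt", paste(sprintf("%.10g", p), collapse = " "))))
  if (!is.null(mesh$texture)) lines <- c(lines, "usemtl material0")
  lines <- c(lines,
             apply(mesh$faces, 1, function(v)
               paste("f", paste(sprintf("%d/%d", v, v), collapse = " "))))
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

export_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply", "format binary_little_endian 1.0",
              paste("element vertex", nv),
              "property double x", "property double y", "property double z",
              "property double u", "property double v",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    vdata <- cbind(mesh$vertices, mesh$uv)
    writeBin(as.numeric(t(vdata)), con, size = 8, endian = "little")
    for (r in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$faces[r, ] - 1L), con, size = 4,
               endian = "little")
    }
  })
}

#' Import a mesh written by [export_mesh()]
#'
#' @param path an OBJ or PLY file produced by this package.
#' @return A [surface_mesh()] (texture not reloaded).
#' @export
import_mesh <- function(path) {
  if (grepl("\\.ply$", path)) import_ply(path) else import_obj(path)
}

import_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    l <- readLines(con, n = 1)
    header <- c(header, l)
    if (l == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  vdata <- matrix(readBin(con, "numeric", n = nv * 5, size = 8,
                          endian = "little"),
                  nrow = nv, byrow = TRUE)
  faces <- matrix(0L, nf, 3)
  for (r in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", n = 1))
    faces[r, ] <- readBin(con, "integer", n = cnt, size = 4,
                          endian = "little") + 1L
  }
  surface_mesh(vdata[, 1:3, drop = FALSE], faces, vdata[, 4:5, drop = FALSE])
}

import_obj <- function(path) {
  lines <- readLines(path)
  num <- function(prefix, k) {
    sel <- grep(paste0("^", prefix, " "), lines, value = TRUE)
    t(vapply(sel, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][-1])[seq_len(k)], numeric(k)))
  }
  v <- num("v", 3)
  vt <- num("vt", 2)
  fsel <- grep("^f ", lines, value = TRUE)
  f <- t(vapply(fsel, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]][-1]
    as.integer(vapply(strsplit(toks, "/"), `[[`, character(1), 1))
  }, integer(3)))
  surface_mesh(v, f, vt)
}
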