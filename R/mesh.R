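## SurfaceMesh: iso-surface extraction from the carved occupancy grid,
## volume-preserving smoothing, mesh metrics, and PLY/STL I/O.

#' Construct a surface mesh
#' @param vertices n x 3 numeric matrix (um, specimen frame).
#' @param faces m x 3 integer matrix of 1-based vertex indices with
#'   consistent outward orientation.
#' @param watertight logical; checked/filled by [extract_mesh()].
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, watertight = NA) {
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces, watertight = watertight),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), x$watertight))
  invisible(x)
}

#' Extract a triangle mesh from a carved volume
#'
#' The binary occupancy grid is smoothed with a 3D Gaussian (`field_sigma`
#' voxels) and the 0.5 iso-surface is extracted by marching tetrahedra on
#' the Kuhn 6-tetrahedron cube decomposition (watertight and consistently
#' oriented by construction), followed by `smooth_iters` passes of Taubin
#' lambda-mu smoothing, which suppresses voxelization ripple while
#' preserving volume. Vertices are in um in the specimen frame.
#'
#' @param vol a `voxel_volume`.
#' @param smooth_iters Taubin smoothing iterations (default 10).
#' @param field_sigma Gaussian pre-smoothing of the occupancy field, voxels.
#' @return a watertight `surface_mesh`. If the extracted surface is not
#'   watertight (cannot happen for tetrahedral decomposition of a padded
#'   grid, but checked defensively) an error is raised.
#' @export
extract_mesh <- function(vol, smooth_iters = 10, field_sigma = 1) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!any(vol$grid)) stopf("cannot mesh an empty volume")
  pad <- max(2L, ceiling(3 * field_sigma))
  d <- dim(vol$grid)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    vol$grid * 1
  field <- gauss3d(field, field_sigma)

  iso <- .mt_isosurface(field, 0.5)
  if (nrow(iso$vertices) == 0) stopf("iso-surface extraction found no surface")
  V <- iso$vertices
  ## lattice coordinate k (0-based) corresponds to grid index k + 1 - pad
  V <- V - pad + 1
  mesh <- surface_mesh(V, iso$faces)
  if (smooth_iters > 0) mesh <- taubin_smooth(mesh, smooth_iters)

  ## voxel index -> um
  x0 <- 0; y0 <- (length(vol$y_um) + 1) / 2
  mesh$vertices <- cbind((mesh$vertices[, 1] - 1) * vol$voxel_um +
                           x0 * vol$voxel_um,
                         (mesh$vertices[, 2] - y0) * vol$voxel_um,
                         (mesh$vertices[, 3] - y0) * vol$voxel_um)
  mesh$watertight <- is_watertight(mesh)
  if (!mesh$watertight) stopf("extracted mesh is not watertight")
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Taubin lambda-mu mesh smoothing (volume-preserving)
#'
#' Alternating Laplacian steps with positive (`lambda`) and negative (`mu`)
#' factors; the negative step counteracts the shrinkage of plain Laplacian
#' smoothing.
#'
#' @param mesh a `surface_mesh`.
#' @param iters number of lambda+mu passes.
#' @param lambda,mu Taubin factors.
#' @return the smoothed `surface_mesh`.
#' @export
taubin_smooth <- function(mesh, iters = 10, lambda = 0.5, mu = -0.53) {
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(V)
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  W <- A / deg
  for (k in seq_len(iters)) {
    V <- V + lambda * (as.matrix(W %*% V) - V)
    V <- V + mu * (as.matrix(W %*% V) - V)
  }
  mesh$vertices <- V
  mesh
}

#' Total surface area of a triangle mesh (sum of triangle areas)
#' @param mesh a `surface_mesh`.
#' @return area in the square of the vertex units (um^2).
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a closed triangle mesh (divergence theorem)
#' @param mesh a `surface_mesh`.
#' @return signed volume (positive for outward orientation), um^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
        v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
        v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Is the mesh watertight (every edge shared by exactly two faces)?
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment units um",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(mesh$vertices[, 1], mesh$vertices[, 2],
                   mesh$vertices[, 3]), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY written by [write_ply()]
#' @param path PLY file.
#' @return a `surface_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vl <- lines[hdr_end + seq_len(nv)]
  V <- matrix(as.numeric(unlist(strsplit(vl, " "))), nv, 3, byrow = TRUE)
  fl <- lines[hdr_end + nv + seq_len(nf)]
  Fm <- matrix(as.integer(unlist(strsplit(fl, " "))), nf, 4, byrow = TRUE)
  mesh <- surface_mesh(V, Fm[, 2:4] + 1L)
  mesh$watertight <- is_watertight(mesh)
  mesh
}

#' Write a mesh as ASCII STL
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @param name solid name in the STL header.
#' @export
write_stl <- function(mesh, path, name = "rotomorph") {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(F))) {
    writeLines(c(sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", V[F[i, 1], 1], V[F[i, 1], 2], V[F[i, 1], 3]),
                 sprintf("    vertex %g %g %g", V[F[i, 2], 1], V[F[i, 2], 2], V[F[i, 2], 3]),
                 sprintf("    vertex %g %g %g", V[F[i, 3], 1], V[F[i, 3], 2], V[F[i, 3], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
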