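## phenotype module: the five 3D morphometric metrics -- surface area,
## volume, length, maximum width, and length/width ratio -- plus
## transverse-section outlines, measured on the reconstructed model.

#' Volume of a carved model
#'
#' Primary estimate: occupied-voxel count times the voxel volume. The mesh
#' divergence-theorem volume is the recommended QC cross-check
#' ([mesh_volume()]).
#'
#' @param vol a `voxel_volume`.
#' @return volume in um^3.
#' @export
measure_volume <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!any(vol$grid)) stopf("empty volume")
  sum(vol$grid) * vol$voxel_um^3
}

#' Surface area of the reconstructed mesh
#' @param mesh a watertight `surface_mesh`.
#' @return area in um^2.
#' @export
measure_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!isTRUE(mesh$watertight)) stopf("mesh must be watertight")
  mesh_area(mesh)
}

#' Extract the centerline of a carved model
#'
#' The body's medial curve: endpoints are found as the geodesically farthest
#' voxel pair (double sweep over the occupied-voxel graph); the raw path is
#' the minimum-cost geodesic between them with node costs inversely
#' proportional to the squared distance-to-surface, which pins the path to
#' the medial axis. The path is refined by snapping each sample to the
#' centroid of its local normal-plane slab, smoothed with cubic smoothing
#' splines per coordinate, resampled uniformly, and extended along the
#' terminal tangents to the surface. Length is the arc length of the
#' extended curve.
#'
#' @param vol a single-component `voxel_volume`.
#' @param n_samples number of uniform arc-length samples returned.
#' @param spar smoothing parameter of [stats::smooth.spline()].
#' @return a `centerline`: `points` (n x 3 um), `tangents` (n x 3 unit),
#'   `length_um`, `arc` (arc positions in `[0,1]`).
#' @export
extract_centerline <- function(vol, n_samples = 200, spar = 0.7) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$grid)
  occ <- as.vector(vol$grid)
  if (!any(occ)) stopf("empty volume")
  dt <- .chamfer_dt(vol$grid, d)

  ## endpoints: euclidean double sweep (centroid -> farthest -> farthest);
  ## graph distances are anisotropically biased on the lattice and would
  ## drag endpoints off-axis
  vox <- vol$voxel_um
  y0 <- (length(vol$y_um) + 1) / 2
  occ_lin <- which(occ)
  oc_all <- arrayInd(occ_lin, d)
  p_all <- cbind((oc_all[, 1] - 1) * vox, (oc_all[, 2] - y0) * vox,
                 (oc_all[, 3] - y0) * vox)
  ctr <- colMeans(p_all)
  ## endpoints: extremes along the body's principal axis, each refined to
  ## the centroid of its end slab (a flat cap's euclidean extreme would be
  ## a rim corner, not the cap centre), then to the nearest occupied voxel
  pc1 <- prcomp(p_all[seq(1, nrow(p_all),
                          by = max(1L, nrow(p_all) %/% 20000L)), ],
                center = TRUE, rank. = 1)$rotation[, 1]
  proj <- drop(sweep(p_all, 2, ctr) %*% pc1)
  end_voxel <- function(side) {
    sel <- if (side > 0) proj >= max(proj) - 1.5 * vox
    else proj <= min(proj) + 1.5 * vox
    target <- colMeans(p_all[sel, , drop = FALSE])
    which.min(rowSums(sweep(p_all, 2, target)^2))
  }
  i1 <- end_voxel(-1)
  i2 <- end_voxel(1)
  e1 <- occ_lin[i1] - 1L
  e2 <- occ_lin[i2] - 1L
  if (e1 == e2) stopf("centerline failure: degenerate skeleton (no endpoints)")

  medial_cost <- 1 / (as.vector(dt) + 0.5)^2
  dp <- .voxel_dijkstra(vol$grid, d, e1, medial_cost)
  path <- integer(0)
  cur <- e2
  while (cur >= 0) {
    path <- c(path, cur)
    cur <- dp$parent[cur + 1L]
  }
  if (length(path) < 4) stopf("centerline failure: path too short")
  ci <- arrayInd(path + 1L, d)
  pts <- cbind((ci[, 1] - 1) * vox, (ci[, 2] - y0) * vox, (ci[, 3] - y0) * vox)
  pts <- pts[nrow(pts):1, , drop = FALSE]

  occupied_at <- function(p) {
    i <- round(p[1] / vox) + 1
    j <- round(p[2] / vox + y0)
    k <- round(p[3] / vox + y0)
    i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3] &&
      vol$grid[i, j, k]
  }
  dt_at <- function(p) {
    i <- clamp(round(p[1] / vox) + 1, 1, d[1])
    j <- clamp(round(p[2] / vox + y0), 1, d[2])
    k <- clamp(round(p[3] / vox + y0), 1, d[3])
    dt[i, j, k]
  }

  ## snap interior samples to local slab centroids (two passes) to undo
  ## lattice zig-zag bias; endpoints stay put (a slab centroid at a cap
  ## pulls inward and would shorten the body)
  occ_idx <- which(vol$grid)
  if (length(occ_idx) > 80000L)
    occ_idx <- occ_idx[seq(1, length(occ_idx), length.out = 80000L)]
  oc <- arrayInd(occ_idx, d)
  opts <- cbind((oc[, 1] - 1) * vox, (oc[, 2] - y0) * vox, (oc[, 3] - y0) * vox)
  ox <- opts[, 1]
  n_guard <- max(2L, ceiling(0.04 * nrow(pts)))
  for (pass in 1:2) {
    tang <- path_tangents(pts)
    for (q in seq((n_guard + 1), nrow(pts) - n_guard)) {
      rmax <- (dt_at(pts[q, ]) + 2) * vox * 1.6
      near <- which(abs(ox - pts[q, 1]) <= rmax + vox)
      if (length(near) < 3) next
      rel <- sweep(opts[near, , drop = FALSE], 2, pts[q, ])
      along <- rel %*% tang[q, ]
      r2 <- rowSums(rel^2) - along^2
      sel <- abs(along) <= vox & r2 <= rmax^2
      if (sum(sel) >= 3)
        pts[q, ] <- colMeans(opts[near[sel], , drop = FALSE])
    }
  }

  ## smooth each coordinate against arc length and resample uniformly
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  keep <- c(TRUE, diff(arc) > 1e-9)
  pts <- pts[keep, , drop = FALSE]; arc <- arc[keep]
  sm <- lapply(1:3, function(j) {
    if (nrow(pts) < 10) return(approx(arc, pts[, j], xout = arc)$y)
    predict(smooth.spline(arc, pts[, j], spar = spar), arc)$y
  })
  pts <- do.call(cbind, sm)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  s_out <- seq(0, max(arc), length.out = n_samples)
  pts <- cbind(approx(arc, pts[, 1], xout = s_out)$y,
               approx(arc, pts[, 2], xout = s_out)$y,
               approx(arc, pts[, 3], xout = s_out)$y)

  ## extend both ends along the terminal tangent to the surface
  extend_end <- function(p, t_hat) {
    step <- vox / 4
    add <- 0
    while (occupied_at(p + (add + step) * t_hat) && add < 50 * vox)
      add <- add + step
    add
  }
  tang <- path_tangents(pts)
  ext_tail <- extend_end(pts[nrow(pts), ], tang[nrow(pts), ])
  ext_head <- extend_end(pts[1, ], -tang[1, ])
  if (ext_head > 0) pts <- rbind(pts[1, ] - ext_head * tang[1, ], pts)
  if (ext_tail > 0) pts <- rbind(pts, pts[nrow(pts), ] + ext_tail * tang[nrow(tang), ])

  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(points = pts, tangents = path_tangents(pts),
                 length_um = max(arc), arc = arc / max(arc)),
            class = "centerline")
}

path_tangents <- function(pts) {
  n <- nrow(pts)
  t <- rbind(pts[2, ] - pts[1, ],
             pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
             pts[n, ] - pts[n - 1, ])
  len <- sqrt(rowSums(t^2)); len[len == 0] <- 1
  t / len
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d samples, length %.1f um\n",
              nrow(x$points), x$length_um))
  invisible(x)
}

## intersection of the mesh with the plane through `point` normal to
## `normal`, restricted to a neighbourhood of the point; returns 2D points
## in the plane basis (e1, e2)
plane_section_points <- function(mesh, point, normal, radius_um = Inf) {
  V <- mesh$vertices; F <- mesh$faces
  ## cheap prefilter: triangles cannot cross the plane near the point if
  ## all their vertices are far from it along any axis
  if (is.finite(radius_um)) {
    near_v <- abs(V[, 1] - point[1]) <= radius_um &
      abs(V[, 2] - point[2]) <= radius_um &
      abs(V[, 3] - point[3]) <= radius_um
    keep_f <- near_v[F[, 1]] | near_v[F[, 2]] | near_v[F[, 3]]
    if (!any(keep_f)) return(NULL)
    F <- F[keep_f, , drop = FALSE]
  }
  sdist <- as.vector(sweep(V, 2, point) %*% normal)
  s1 <- sdist[F[, 1]]; s2 <- sdist[F[, 2]]; s3 <- sdist[F[, 3]]
  crossing <- !(s1 > 0 & s2 > 0 & s3 > 0) & !(s1 < 0 & s2 < 0 & s3 < 0)
  if (!any(crossing)) return(NULL)
  Fc <- F[crossing, , drop = FALSE]
  pts <- list()
  for (i in seq_len(nrow(Fc))) {
    tri <- Fc[i, ]
    sv <- sdist[tri]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- sv[e[1]]; b <- sv[e[2]]
      if ((a > 0) != (b > 0)) {
        t <- a / (a - b)
        pts[[length(pts) + 1]] <-
          V[tri[e[1]], ] + t * (V[tri[e[2]], ] - V[tri[e[1]], ])
      }
    }
  }
  if (!length(pts)) return(NULL)
  P <- do.call(rbind, pts)
  keep <- rowSums(sweep(P, 2, point)^2) <= radius_um^2
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 3) return(NULL)
  ## plane basis
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  rel <- sweep(P, 2, point)
  cbind(rel %*% e1, rel %*% e2)
}

#' Maximum body width from normal cross-sections
#'
#' At each centerline sample the mesh is sliced by the plane normal to the
#' local tangent; the section width is its maximal Feret (caliper) diameter.
#' The maximum width is the largest section width, excluding the terminal
#' `exclude_frac` of arc length at each end where cap geometry dominates.
#'
#' @param vol a `voxel_volume` (used for the local radius bound).
#' @param mesh the extracted `surface_mesh`.
#' @param centerline a [extract_centerline()] result with >= 10 samples.
#' @param n_samples number of arc positions probed.
#' @param exclude_frac terminal arc fraction excluded at each end.
#' @return list `max_width_um`, `arc_position` (of the maximum), `widths`
#'   (data.frame arc, width_um).
#' @export
measure_max_width <- function(vol, mesh, centerline, n_samples = 100,
                              exclude_frac = 0.05) {
  stopifnot(inherits(centerline, "centerline"))
  if (nrow(centerline$points) < 10) stopf("centerline needs >= 10 samples")
  s <- seq(exclude_frac, 1 - exclude_frac, length.out = n_samples)
  w <- vapply(s, function(si) {
    cs <- cross_section_at(vol, mesh, centerline, si)
    if (is.null(cs)) return(NA_real_)
    max_feret(cs)
  }, numeric(1))
  if (all(is.na(w))) stopf("no valid cross-section found")
  ## running median guards against single oblique-cut outliers
  ws <- w
  ok <- !is.na(w)
  if (sum(ok) >= 7) ws[ok] <- stats::runmed(w[ok], 5, endrule = "median")
  k <- which.max(ws)
  list(max_width_um = ws[k], arc_position = s[k],
       widths = data.frame(arc = s, width_um = w, width_smooth_um = ws))
}

## section of the mesh at arc position s, restricted to the local body
cross_section_at <- function(vol, mesh, centerline, s) {
  p <- centerline_point(centerline, s)
  ## local radius bound from the chamfer DT at the point
  r_loc <- local_radius(vol, p$point) * vol$voxel_um
  plane_section_points(mesh, p$point, p$tangent,
                       radius_um = max(4 * r_loc, 6 * vol$voxel_um))
}

centerline_point <- function(cl, s) {
  s <- clamp(s, 0, 1)
  j <- findInterval(s, cl$arc, all.inside = TRUE)
  t <- (s - cl$arc[j]) / max(cl$arc[j + 1] - cl$arc[j], 1e-12)
  point <- cl$points[j, ] + t * (cl$points[j + 1, ] - cl$points[j, ])
  tangent <- cl$tangents[j, ] + t * (cl$tangents[j + 1, ] - cl$tangents[j, ])
  tangent <- tangent / sqrt(sum(tangent^2))
  list(point = point, tangent = tangent)
}

local_radius <- function(vol, p) {
  d <- dim(vol$grid)
  y0 <- (length(vol$y_um) + 1) / 2
  dt <- attr(vol, "dt_cache")
  if (is.null(dt)) dt <- .chamfer_dt(vol$grid, d)
  i <- clamp(round(p[1] / vol$voxel_um) + 1, 1, d[1])
  j <- clamp(round(p[2] / vol$voxel_um + y0), 1, d[2])
  k <- clamp(round(p[3] / vol$voxel_um + y0), 1, d[3])
  max(dt[i, j, k], 1)
}

#' Transverse-section outline at an arc position
#'
#' @param vol a `voxel_volume`.
#' @param mesh the extracted `surface_mesh`.
#' @param centerline a [extract_centerline()] result.
#' @param arc_position fraction of arc length in `[0, 1]`.
#' @return a closed, angularly ordered outline: (k+1) x 2 matrix of planar
#'   coordinates (um) whose first and last points coincide.
#' @export
cross_section <- function(vol, mesh, centerline, arc_position) {
  if (arc_position < 0 || arc_position > 1)
    stopf("arc_position must be in [0, 1]")
  pts <- cross_section_at(vol, mesh, centerline, arc_position)
  if (is.null(pts)) stopf("no section found at arc position %.2f", arc_position)
  ctr <- colMeans(pts)
  ord <- order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]))
  out <- pts[ord, , drop = FALSE]
  rbind(out, out[1, , drop = FALSE])
}

#' Assemble the five-metric morphometric record of one specimen
#'
#' @param vol a `voxel_volume`.
#' @param mesh the extracted `surface_mesh`.
#' @param sample_id,strain,stage specimen annotation (stage is `"embryo"`
#'   or `"adult"`).
#' @param qc_mean_iou reconstruction QC: the mean reprojection IoU.
#' @param centerline optionally a precomputed [extract_centerline()].
#' @return a one-row data.frame of class `morphometric_record` with the
#'   five metrics (`surface_area_um2`, `volume_um3`, `length_um`,
#'   `max_width_um`, `ratio`) plus annotation and QC.
#' @export
phenotype <- function(vol, mesh, sample_id = "specimen", strain = NA_character_,
                      stage = c("adult", "embryo"), qc_mean_iou = NA_real_,
                      centerline = NULL) {
  stage <- match.arg(stage)
  cl <- centerline %||% extract_centerline(vol)
  wid <- measure_max_width(vol, mesh, cl)
  rec <- data.frame(sample_id = sample_id, strain = strain, stage = stage,
                    surface_area_um2 = measure_surface_area(mesh),
                    volume_um3 = measure_volume(vol),
                    length_um = cl$length_um,
                    max_width_um = wid$max_width_um,
                    ratio = cl$length_um / wid$max_width_um,
                    qc_mean_iou = qc_mean_iou,
                    stringsAsFactors = FALSE)
  if (any(rec[, 4:8] <= 0)) stopf("morphometric record has non-positive metrics")
  class(rec) <- c("morphometric_record", class(rec))
  rec
}

#' Append morphometric records to a CSV (one row per specimen)
#' @param records a `morphometric_record` (or data.frame of them).
#' @param path CSV path; created with a header when absent.
#' @export
append_records_csv <- function(records, path) {
  new <- !file.exists(path)
  suppressWarnings(
    write.table(records, path, sep = ",", append = !new, col.names = new,
                row.names = FALSE))
  invisible(path)
}
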