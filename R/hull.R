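## hull module: shape-from-silhouette reconstruction. The volume is carved
## in the specimen's co-rotating frame: grid x = rotation axis (image
## columns), (y, z) = cross-section plane with the axis at its centre. A
## point (y, z) projects to the image-vertical offset y*cos(theta) +
## z*sin(theta) at rotation angle theta; the silhouette's vertical interval
## at each column therefore constrains a strip in the (y, z) plane, and the
## cross-section is the intersection of the strips of all contributing
## frames. A frame contributes to an axial slice only when the slice lies
## inside the frame's confident extent -- silhouette columns never observed
## with sufficient contrast (the faint tail) impose no constraint, which is
## what reconstructs the missing tail features.

## shared grid geometry so the slicewise and brute-force carvers operate on
## the identical voxel lattice
carve_geometry <- function(sils, frames, margin = 2) {
  px <- sils$pixel_size_um
  nc <- dim(sils$masks)[2]
  nr <- dim(sils$masks)[1]
  supp <- which(apply(sils$masks[, , frames, drop = FALSE], 2, any))
  if (!length(supp)) stopf("no silhouette support in the selected frames")
  cols <- max(1L, min(supp) - margin):min(nc, max(supp) + margin)
  ## strip bounds per frame (um, relative to the rotation axis), NA = empty;
  ## sub-pixel boundary estimates are used when the segmentation provides
  ## them, else the binary mask rows +/- half a pixel
  bounds <- lapply(frames, function(i) {
    ry <- sils$resid[i, "ry"]
    if (!is.null(sils$sub_lo)) {
      lo <- (sils$sub_lo[cols, i] - sils$axis_row + ry) * px
      hi <- (sils$sub_hi[cols, i] - sils$axis_row + ry) * px
      return(list(lo = lo, hi = hi))
    }
    m <- sils$masks[, , i]
    lo <- rep(NA_real_, length(cols)); hi <- lo
    idx <- which(m[, cols, drop = FALSE], arr.ind = TRUE)
    if (nrow(idx)) {
      rmin <- tapply(idx[, 1], idx[, 2], min)
      rmax <- tapply(idx[, 1], idx[, 2], max)
      j <- as.integer(names(rmin))
      lo[j] <- (rmin - 0.5 - sils$axis_row + ry) * px
      hi[j] <- (rmax + 0.5 - sils$axis_row + ry) * px
    }
    list(lo = lo, hi = hi)
  })
  H <- max(vapply(bounds, function(b)
    max(abs(c(b$lo, b$hi)), na.rm = TRUE), numeric(1)))
  ## mean strip height per column (px) across frames, for the
  ## uncertainty-scaled quorum
  hbar <- rep(NA_real_, length(cols))
  hsum <- rep(0, length(cols)); hn <- rep(0L, length(cols))
  for (b in bounds) {
    okb <- !is.na(b$lo)
    hsum[okb] <- hsum[okb] + (b$hi[okb] - b$lo[okb]) / px
    hn[okb] <- hn[okb] + 1L
  }
  hbar[hn > 0] <- hsum[hn > 0] / hn[hn > 0]
  list(cols = cols, bounds = bounds, px = px, nr = nr, nc = nc, H = H,
       hbar = hbar)
}


## uncertainty-scaled quorum: the fraction of strip constraints a voxel may
## violate grows where the strips are thin, because a fixed silhouette
## boundary noise (a fraction of a pixel) is large relative to a thin
## feature; miss_frac is the floor for wide, well-constrained sections
quorum_need <- function(contrib, hbar_px, miss_frac) {
  miss <- clamp(0.5 / pmax(hbar_px, 0.5), miss_frac, 0.3)
  miss[is.na(miss)] <- miss_frac
  pmax(ceiling((1 - miss) * contrib), 1L)
}

new_voxel_volume <- function(grid, voxel_um, cols, y_um, axis_row, nr, nc, px) {
  ## carving is per image column (x pitch = pixel size); when a finer
  ## cross-section pitch is requested, each column's cross-section is
  ## replicated along x so the stored grid is isotropic (the hull carries
  ## no sub-column x information anyway)
  k <- px / voxel_um
  if (abs(k - round(k)) > 1e-6)
    stopf("voxel_um must divide the pixel size (%g / %g)", px, voxel_um)
  k <- as.integer(round(k))
  if (k > 1L) {
    grid <- grid[rep(seq_len(dim(grid)[1]), each = k), , , drop = FALSE]
    cols <- rep(cols, each = k)
  }
  structure(list(grid = grid, voxel_um = voxel_um,
                 cols = cols, y_um = y_um, z_um = y_um,
                 axis_row = axis_row, img_dim = c(nr, nc),
                 pixel_size_um = px), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels at %.3g um, %d occupied (%.4g um^3)\n",
              d[1], d[2], d[3], x$voxel_um, sum(x$grid),
              sum(x$grid) * x$voxel_um^3), sep = "")
  invisible(x)
}

#' Carve the visual hull slice by slice
#'
#' For each axial slice the cross-section is the intersection, over
#' contributing frames, of the strips defined by the silhouette's vertical
#' interval at that column. Silhouette columns with multiple vertical runs
#' use the full min-max span (the conservative hull; runs cannot be matched
#' across angles). Slices with no contributing frame stay empty. After
#' carving, the largest 6-connected component is kept.
#'
#' @param sils an aligned, angle-stamped `silhouette_stack`.
#' @param voxel_um voxel pitch; defaults to the mask pixel size (isotropic).
#' @param gate_extent apply confident-extent gating (the feature-completion
#'   rule)? Disabling it lets unseen tail columns carve, which visibly
#'   truncates faded tails; exposed for ablation.
#' @param n_min minimum number of angle-stamped frames.
#' @param margin grid margin around the silhouettes' bounding box, voxels.
#' @param min_contrib minimum number of contributing frames an axial slice
#'   needs before its cross-section is kept.
#' @param miss_frac quorum tolerance: fraction of contributing constraints
#'   a voxel may violate and still survive (robustness to single noisy
#'   silhouette boundaries).
#' @return a `voxel_volume`.
#' @export
carve_slicewise <- function(sils, voxel_um = NULL, gate_extent = TRUE,
                            n_min = 12, margin = 2, min_contrib = 8,
                            miss_frac = 0.02) {
  stopifnot(inherits(sils, "silhouette_stack"))
  frames <- which(sils$selected & !sils$failed & !is.na(sils$angles_rad))
  if (length(frames) < n_min)
    stopf("need >= %d angle-stamped frames, have %d", n_min, length(frames))
  g <- carve_geometry(sils, frames, margin)
  vox <- voxel_um %||% g$px
  m <- ceiling((g$H + margin * vox) / vox)
  y_um <- (-m:m) * vox
  ncell <- length(y_um)^2
  Y <- rep(y_um, times = length(y_um))
  Z <- rep(y_um, each = length(y_um))
  nxs <- length(g$cols)

  ok <- matrix(0L, ncell, nxs)
  contrib <- integer(nxs)
  for (f in seq_along(frames)) {
    i <- frames[f]
    th <- sils$angles_rad[i]
    pvec <- Y * cos(th) + Z * sin(th)
    use <- if (gate_extent)
      g$cols >= sils$extent[i, 1] & g$cols <= sils$extent[i, 2]
    else rep(TRUE, nxs)
    if (!any(use)) next
    .carve_accum(ok, pvec, g$bounds[[f]]$lo, g$bounds[[f]]$hi, use)
    contrib[use] <- contrib[use] + 1L
  }
  ## quorum intersection: a voxel survives when it satisfies all but a
  ## small fraction of the contributing strip constraints; a strict
  ## intersection is brittle for thin features (one noisy silhouette
  ## boundary in any of the frames would erase a sub-resolution tail tip)
  need <- quorum_need(contrib, g$hbar, miss_frac)
  alive <- sweep(ok, 2, need, ">=")
  ## a cross-section constrained by only a handful of strips is essentially
  ## unconstrained (two strips intersect in an unbounded-looking rhomb);
  ## such slices are left empty rather than bloated
  alive[, contrib < max(1L, min_contrib)] <- FALSE

  grid <- aperm(array(alive, c(length(y_um), length(y_um), nxs)), c(3, 1, 2))
  if (!any(grid)) {
    diag_df <- data.frame(col = g$cols, contributing = contrib)
    stopf("reconstruction failure: carved volume is empty (%d/%d slices had contributing frames)",
          sum(diag_df$contributing > 0), nrow(diag_df))
  }
  grid <- array(.largest_component(grid, dim(grid)), dim(grid))
  new_voxel_volume(grid, vox, g$cols, y_um, sils$axis_row, g$nr, g$nc, g$px)
}

#' Brute-force visual hull carving (independent oracle)
#'
#' Full 3D carving: a voxel survives iff, for every contributing frame, its
#' rotated orthographic projection lands on a foreground pixel of that
#' frame's mask (nearest-pixel lookup). Gating is identical to
#' [carve_slicewise()]; on masks whose columns are single vertical runs the
#' two carvers agree voxel for voxel. Intended for testing; quadratic cost.
#'
#' @inheritParams carve_slicewise
#' @return a `voxel_volume`.
#' @export
carve_bruteforce <- function(sils, voxel_um = NULL, gate_extent = TRUE,
                             n_min = 1, margin = 2, min_contrib = 1,
                             miss_frac = 0.02) {
  stopifnot(inherits(sils, "silhouette_stack"))
  frames <- which(sils$selected & !sils$failed & !is.na(sils$angles_rad))
  if (length(frames) < max(1, n_min)) stopf("no angle-stamped frames to carve from")
  g <- carve_geometry(sils, frames, margin)
  vox <- voxel_um %||% g$px
  m <- ceiling((g$H + margin * vox) / vox)
  y_um <- (-m:m) * vox
  nyz <- length(y_um)
  nxs <- length(g$cols)

  Xc <- rep(seq_len(nxs), times = nyz * nyz)
  Yc <- rep(rep(y_um, each = nxs), times = nyz)
  Zc <- rep(y_um, each = nxs * nyz)
  okc <- integer(length(Xc))
  contrib <- integer(length(Xc))
  nr <- g$nr

  for (f in seq_along(frames)) {
    i <- frames[f]
    th <- sils$angles_rad[i]
    v <- Yc * cos(th) + Zc * sin(th)
    u <- v / g$px + sils$axis_row - sils$resid[i, "ry"]
    colp <- g$cols[Xc]
    use <- if (gate_extent)
      colp >= sils$extent[i, 1] & colp <= sils$extent[i, 2]
    else rep(TRUE, length(Xc))
    if (!is.null(sils$sub_lo)) {
      lo <- sils$sub_lo[colp, i]; hi <- sils$sub_hi[colp, i]
      hit <- !is.na(lo) & u >= lo & u <= hi
    } else {
      msk <- sils$masks[, , i]
      r <- floor(u + 0.5)
      inside <- r >= 1 & r <= nr
      hit <- rep(FALSE, length(Xc))
      hit[inside] <- msk[cbind(r[inside], colp[inside])]
    }
    okc <- okc + (use & hit)
    contrib <- contrib + use
  }
  alive <- okc >= quorum_need(contrib, g$hbar[Xc], miss_frac) &
    contrib >= max(1L, min_contrib)
  grid <- array(FALSE, c(nxs, nyz, nyz))
  grid[cbind(Xc, match(Yc, y_um), match(Zc, y_um))] <- alive
  if (!any(grid)) stopf("reconstruction failure: carved volume is empty")
  grid <- array(.largest_component(grid, dim(grid)), dim(grid))
  new_voxel_volume(grid, vox, g$cols, y_um, sils$axis_row, g$nr, g$nc, g$px)
}
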