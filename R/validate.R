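## validate module: reproject the carved model at chosen viewpoints and
## score reprojection IoU against the segmented frames at corresponding
## orientations -- the accuracy metric of the reconstruction.

#' Orthographically reproject a carved volume at a rotation angle
#'
#' The grid is rotated by the angle about the x (rotation) axis and
#' projected along the optical axis onto the raster geometry of the aligned
#' masks. Cross-sections of a visual hull are convex (intersections of
#' strips), so each slice projects to a contiguous vertical pixel run.
#'
#' @param vol a `voxel_volume`.
#' @param angle_deg viewpoint angle, degrees.
#' @param resid_y sub-pixel vertical residual (px) of the frame being
#'   compared against, as stored by [align_frames()]; carving applied it to
#'   the strip bounds, so reprojection must apply the same shift to land on
#'   that frame's raster.
#' @return a logical mask with the mask raster dimensions.
#' @export
reproject <- function(vol, angle_deg, resid_y = 0) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!any(vol$grid)) stopf("cannot reproject an empty volume")
  th <- angle_deg * pi / 180
  nr <- vol$img_dim[1]; nc <- vol$img_dim[2]
  px <- vol$pixel_size_um
  ## project voxel centres with no extra margin: the carving strips already
  ## carry the +/- half-pixel footprint of the silhouette rows, so the
  ## surviving centres reach exactly the outer pixel bound; adding a margin
  ## here would spill the silhouette one row outward at oblique angles
  h <- 0
  ny <- length(vol$y_um)
  P <- rep(vol$y_um, times = ny) * cos(th) +
    rep(vol$z_um, each = ny) * sin(th)
  mask <- matrix(FALSE, nr, nc)
  eps <- 1e-6
  for (i in seq_len(dim(vol$grid)[1])) {
    occ <- as.vector(vol$grid[i, , ])
    if (!any(occ)) next
    v <- P[occ]
    u_lo <- (min(v) - h) / px + vol$axis_row - resid_y
    u_hi <- (max(v) + h) / px + vol$axis_row - resid_y
    r0 <- max(1L, as.integer(ceiling(u_lo - 0.5 + eps)))
    r1 <- min(nr, as.integer(floor(u_hi + 0.5 - eps)))
    if (r0 <= r1) mask[r0:r1, vol$cols[i]] <- TRUE
  }
  mask
}

#' Intersection over union of two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return IoU in `[0, 1]`; raising an error when both masks are empty
#'   (the ratio is undefined).
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("masks must have the same shape")
  u <- sum(a | b)
  if (u == 0) stopf("IoU undefined: both masks are empty")
  sum(a & b) / u
}

#' Validate a reconstruction by reprojection IoU
#'
#' Reprojects the model at each requested viewpoint and scores IoU against
#' the segmented frame whose assigned angle is nearest (no interpolation);
#' a viewpoint with no frame within half an inter-frame step is skipped
#' with a warning. The default viewpoints span 0 to 180 degrees in steps
#' of 30.
#'
#' @param vol a `voxel_volume`.
#' @param sils the angle-stamped `silhouette_stack` used for carving.
#' @param viewpoints_deg numeric vector of viewpoint angles, degrees.
#' @return an `iou_report`: data.frame `per_view` (viewpoint, frame,
#'   frame angle, IoU), `mean`, `sd`, `n`.
#' @export
validate_reconstruction <- function(vol, sils,
                                    viewpoints_deg = seq(0, 180, by = 30)) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(sils, "silhouette_stack"))
  frames <- which(sils$selected & !is.na(sils$angles_rad))
  if (!length(frames)) stopf("no angle-stamped frames to validate against")
  fr_deg <- sils$angles_rad[frames] * 180 / pi
  step <- 360 / sils$period_frames

  rows <- lapply(viewpoints_deg, function(vp) {
    d <- ang_dist_deg(fr_deg, vp)
    j <- which.min(d)
    if (d[j] > step / 2 + 1e-9) {
      warnf("no frame within half a step of viewpoint %g deg; skipped", vp)
      return(NULL)
    }
    f <- frames[j]
    pred <- reproject(vol, fr_deg[j], resid_y = sils$resid[f, "ry"])
    data.frame(viewpoint_deg = vp, frame = f, frame_angle_deg = fr_deg[j],
               iou = iou(pred, sils$masks[, , f]))
  })
  per_view <- do.call(rbind, rows)
  if (is.null(per_view) || nrow(per_view) == 0)
    stopf("no viewpoint could be matched to a frame")
  structure(list(per_view = per_view, mean = mean(per_view$iou),
                 sd = if (nrow(per_view) > 1) sd(per_view$iou) else NA_real_,
                 n = nrow(per_view)), class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("<iou_report> mean IoU %.4f +/- %.4f over %d viewpoints\n",
              x$mean, x$sd, x$n))
  print(x$per_view, row.names = FALSE)
  invisible(x)
}

#' Write an IoU report as JSON and CSV
#' @param report an `iou_report`.
#' @param path_json,path_csv output files (either may be `NULL`).
#' @export
write_iou_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(list(mean = report$mean, sd = report$sd,
                              n = report$n, per_view = report$per_view),
                         path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv))
    write.csv(report$per_view, path_csv, row.names = FALSE)
  invisible(report)
}
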