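## kinematics module: rotation-period estimation by template matching
## (normalized cross-correlation between frames at increasing lags), frame
## alignment (drift removal), and angle assignment under the
## uniform-rotation assumption.

#' Estimate the rotation period by template matching
#'
#' The similarity between frames `i` and `i + lag` is their normalized
#' cross-correlation (NCC), averaged over all valid `i`; the period is the
#' lag maximizing this curve, refined to sub-frame precision by 3-point
#' parabolic interpolation and, when the stack holds several full periods,
#' averaged across the harmonic peaks near `2p, 3p, ...`. NCC is computed on
#' intensity frames rather than masks: internal landmarks break the
#' near-symmetries of the silhouette (a rotationally symmetric mask is the
#' same at every angle). NCC makes the estimate invariant to global
#' intensity scaling and offsets.
#'
#' @param x an [image_stack()] (recommended) or a `silhouette_stack`.
#' @param min_lag,max_lag search range in frames; defaults `8` and `T - 4`.
#' @param s_min minimum acceptable peak NCC; below it (or for a flat
#'   similarity curve) the rotation is declared unreliable.
#' @return an object of class `rotation_estimate`: `period_frames`,
#'   `angles_rad` (one per frame, `2*pi*(i-1)/period`), `similarity`
#'   (data.frame of lag and score), `peak_score`, `ref_frame`.
#' @export
estimate_period <- function(x, min_lag = 8, max_lag = NULL, s_min = 0.6) {
  frames <- if (inherits(x, "image_stack")) x$frames
  else if (inherits(x, "silhouette_stack")) x$masks * 1
  else stopf("x must be an image_stack or silhouette_stack")
  d <- dim(frames)
  nT <- d[3]
  max_lag <- max_lag %||% (nT - 4L)
  if (!(nT > max_lag && max_lag > min_lag && min_lag >= 4))
    stopf("need T > max_lag > min_lag >= 4 (T = %d)", nT)

  ncc_matrix <- function(F) {
    mu <- colMeans(F)
    F <- sweep(F, 2, mu)
    nrm <- sqrt(colSums(F^2))
    if (any(nrm < 1e-12))
      stopf("no reliable rotation detected: constant frames")
    crossprod(sweep(F, 2, nrm, "/"))
  }
  curve_of <- function(C) vapply(min_lag:max_lag, function(l) {
    i <- seq_len(nT - l)
    mean(C[cbind(i, i + l)])
  }, numeric(1))

  F_raw <- matrix(frames, d[1] * d[2], nT)
  ## peak localization uses mean-subtracted, lightly smoothed frames: the
  ## static silhouette correlates at every lag and would flatten the curve,
  ## while what remains -- the rotating internal texture -- carries the
  ## period; light smoothing suppresses (possibly sharpened) pixel noise
  F_loc <- vapply(seq_len(nT), function(i)
    as.vector(gauss_blur_fft(frames[, , i], 2)), numeric(d[1] * d[2]))
  F_loc <- F_loc - rowMeans(F_loc)
  sim <- curve_of(ncc_matrix(F_loc))
  lags <- min_lag:max_lag

  if (diff(range(sim)) < 0.02)
    stopf("no reliable rotation detected: flat similarity curve")
  k <- which.max(sim)
  ## reliability score: raw-frame NCC at the matched lag (do the frames one
  ## period apart actually look alike?)
  C_raw <- ncc_matrix(F_raw)
  i <- seq_len(nT - lags[k])
  peak_score <- mean(C_raw[cbind(i, i + lags[k])])
  if (peak_score < s_min)
    stopf("no reliable rotation detected: peak NCC %.2f < %.2f",
          peak_score, s_min)

  refine <- function(k) {
    if (k <= 1 || k >= length(lags)) return(lags[k])
    y1 <- sim[k - 1]; y2 <- sim[k]; y3 <- sim[k + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < 1e-12) return(lags[k])
    lags[k] + 0.5 * (y1 - y3) / den
  }
  p1 <- refine(k)

  ## octave correction: if half the chosen lag is itself a comparable
  ## peak, the true period is the subharmonic (noise can favour the
  ## double-period peak, which has fewer frame pairs)
  repeat {
    half <- p1 / 2
    if (half < min_lag) break
    cand <- which(abs(lags - half) <= max(2, 0.05 * half))
    if (!length(cand)) break
    kk <- cand[which.max(sim[cand])]
    if (sim[kk] < 0.8 * sim[k]) break
    k <- kk
    p1 <- refine(kk)
  }

  ## average over harmonic peaks (multiple full periods in the stack)
  ests <- p1; wts <- 1
  h <- 2
  while (h * p1 <= max_lag - 2) {
    centre <- h * p1
    cand <- which(abs(lags - centre) <= max(2, 0.05 * p1))
    if (length(cand)) {
      kk <- cand[which.max(sim[cand])]
      if (sim[kk] > 0.5 * peak_score) {
        ests <- c(ests, refine(kk) / h)
        wts <- c(wts, h)
      }
    }
    h <- h + 1
  }
  period <- sum(ests * wts) / sum(wts)

  structure(list(period_frames = period,
                 angles_rad = (2 * pi * (0:(nT - 1)) / period) %% (2 * pi),
                 similarity = data.frame(lag = lags, score = sim),
                 peak_score = clamp(peak_score, 0, 1),
                 ref_frame = 1L), class = "rotation_estimate")
}

#' @export
print.rotation_estimate <- function(x, ...) {
  cat(sprintf("<rotation_estimate> period %.3f frames (peak NCC %.3f)\n",
              x$period_frames, x$peak_score))
  invisible(x)
}

#' Remove in-plane drift by centroid alignment
#'
#' The drift trend of the mask centroid is estimated by a centered running
#' mean over one rotation period (so the periodic centroid oscillation of a
#' bent body -- which encodes shape, not drift -- is preserved), and each
#' frame is shifted by an integer number of pixels so the trend sits at the
#' stack-median x-centroid and at the rotation-axis row (the mean y-centroid
#' over a period). Sub-pixel residuals are stored and applied during carving
#' by shifting silhouette strip bounds, not by resampling masks.
#'
#' @param sils a `silhouette_stack`.
#' @param period_frames rotation period used for the trend window; when `NA`
#'   the full-stack mean is used.
#' @return the aligned `silhouette_stack` with `offsets`, `resid` and
#'   `axis_row` filled in.
#' @export
align_frames <- function(sils, period_frames = NA) {
  stopifnot(inherits(sils, "silhouette_stack"))
  ok <- !sils$failed
  if (!any(ok)) stopf("all frames failed segmentation; cannot align")
  nT <- dim(sils$masks)[3]

  trend <- function(v) {
    ## drift trend of the centroid trace. The trace is (periodic shape
    ## oscillation) + (slow drift); with the period known the oscillation
    ## is captured by first and second harmonics and the drift by a cubic,
    ## so the trend has no edge bias (a running mean would leak the
    ## oscillation into the drift estimate near the stack ends)
    vv <- v
    if (any(is.na(vv)))
      vv <- approx(which(!is.na(vv)), vv[!is.na(vv)], xout = seq_len(nT),
                   rule = 2)$y
    i <- seq_len(nT)
    if (is.na(period_frames) || nT < 16) return(rep(mean(vv), nT))
    w <- 2 * pi * i / period_frames
    X <- cbind(1, i, i^2, i^3, cos(w), sin(w), cos(2 * w), sin(2 * w))
    fit <- stats::lm.fit(X, vv)
    drop(X[, 1:4, drop = FALSE] %*% fit$coefficients[1:4])
  }

  ty <- trend(ifelse(ok, sils$centroid[, "cy"], NA))
  tx <- trend(ifelse(ok, sils$centroid[, "cx"], NA))
  axis_row <- round(mean(ty[ok]))
  x_target <- median(tx[ok])

  dy <- round(axis_row - ty)
  dx <- round(x_target - tx)
  resid_y <- (axis_row - ty) - dy
  resid_x <- (x_target - tx) - dx

  for (i in which(ok)) {
    if (dy[i] != 0 || dx[i] != 0) {
      sils$masks[, , i] <- shift_matrix(sils$masks[, , i], dy[i], dx[i])
      sils$confidence[, i] <- shift_vector(sils$confidence[, i], dx[i])
      sils$sub_lo[, i] <- shift_vector(sils$sub_lo[, i], dx[i],
                                       fill = NA_real_) + dy[i]
      sils$sub_hi[, i] <- shift_vector(sils$sub_hi[, i], dx[i],
                                       fill = NA_real_) + dy[i]
      sils$extent[i, ] <- clamp(sils$extent[i, ] + dx[i], 1,
                                dim(sils$masks)[2])
      sils$centroid[i, ] <- sils$centroid[i, ] + c(dy[i], dx[i])
    }
  }
  sils$offsets <- cbind(dy = as.integer(dy), dx = as.integer(dx))
  sils$resid <- cbind(ry = resid_y, rx = resid_x)
  sils$axis_row <- axis_row
  sils
}

shift_vector <- function(v, d, fill = 0) {
  out <- rep(fill, length(v))
  src <- seq_along(v) - d
  keep <- src >= 1 & src <= length(v)
  out[which(keep)] <- v[src[keep]]
  out
}

#' Stamp one full period of frames with rotation angles
#'
#' Selects the frames of exactly one rotation period starting at the
#' reference frame and assigns `angle[i] = 2*pi*(i - ref)/period_frames`
#' (uniform rotation). Frames beyond one full turn, and failed frames, are
#' left unselected.
#'
#' @param est a [estimate_period()] result.
#' @param sils an aligned `silhouette_stack`.
#' @param ref reference frame index (angle 0).
#' @param n_min minimum number of usable frames in the window.
#' @return the `silhouette_stack` with `angles_rad`, `selected` and
#'   `period_frames` filled in.
#' @export
assign_angles <- function(est, sils, ref = NULL, n_min = 12) {
  stopifnot(inherits(est, "rotation_estimate"),
            inherits(sils, "silhouette_stack"))
  ref <- ref %||% est$ref_frame
  nT <- dim(sils$masks)[3]
  P <- est$period_frames
  if (ref + ceiling(P) - 1 > nT)
    stopf("window of one period (%.1f frames from frame %d) does not fit in the stack",
          P, ref)
  idx <- ref:(ref + ceiling(P) - 1)
  idx <- idx[idx - ref < P] # angles strictly below 2*pi
  usable <- idx[!sils$failed[idx]]
  if (length(usable) < n_min)
    stopf("only %d usable frames in the rotation window (need >= %d)",
          length(usable), n_min)
  sils$angles_rad[] <- NA_real_
  sils$angles_rad[usable] <- 2 * pi * (usable - ref) / P
  sils$selected[] <- FALSE
  sils$selected[usable] <- TRUE
  sils$period_frames <- P
  sils
}

#' Export the similarity-vs-lag diagnostic curve
#' @param est a `rotation_estimate`.
#' @param path CSV output path.
#' @export
write_similarity_csv <- function(est, path) {
  write.csv(est$similarity, path, row.names = FALSE)
  invisible(path)
}
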