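## imaging module: classical enhancement (background flattening,
## edge-preserving denoise, optional upsampling) and silhouette segmentation
## with per-column confidence and confidence-gated extents.

#' Enhance a frame stack
#'
#' A deterministic classical stand-in for learned super-resolution and
#' denoising: per frame, a smooth background field is estimated (blockwise
#' upper quantile, smoothed), subtracted and replaced by its mean; noise is
#' reduced with a 3x3 median filter; the acquisition PSF is compensated by
#' Wiener deconvolution, which restores near-sharp silhouette edges so the
#' downstream boundary threshold becomes insensitive to its exact level;
#' an optional upsample increases nominal resolution. The output pixel
#' size is the input pixel size divided by `upsample_factor`.
#'
#' @param stack an [image_stack()].
#' @param upsample_factor 1, 2 or 4.
#' @param denoise apply the median filter?
#' @param block_px block size of the background estimator, px.
#' @param bg_quantile quantile used as the per-block background level
#'   (specimens are darker than background, so an upper quantile is robust
#'   to the specimen).
#' @param deconv_sigma_px Gaussian PSF width compensated by the Wiener
#'   filter, px at the input resolution; 0 disables deconvolution.
#' @param wiener_k Wiener regularization constant (noise-to-signal power).
#' @param unsharp_amount strength of post-upsample unsharp masking.
#' @return an enhanced [image_stack()].
#' @export
enhance <- function(stack, upsample_factor = 1, denoise = TRUE,
                    block_px = 16, bg_quantile = 0.8,
                    deconv_sigma_px = 1.2, wiener_k = 0.05,
                    unsharp_amount = 0) {
  stopifnot(inherits(stack, "image_stack"))
  if (!upsample_factor %in% c(1, 2, 4))
    stopf("upsample_factor must be 1, 2 or 4")
  d <- dim(stack$frames)
  out <- vector("list", d[3])
  for (i in seq_len(d[3])) {
    f <- stack$frames[, , i]
    bg <- estimate_background(f, block_px, bg_quantile)
    f <- f - bg + mean(bg)
    if (denoise) f <- .median3x3(clamp(f, 0, 1))
    if (upsample_factor > 1) {
      f <- EBImage::resize(f, w = nrow(f) * upsample_factor,
                           h = ncol(f) * upsample_factor)
      if (unsharp_amount > 0)
        f <- f + unsharp_amount * (f - EBImage::gblur(f, sigma = 1,
                                                      boundary = "replicate"))
    }
    ## deconvolve at the final resolution so the interpolation kernel is
    ## compensated along with the PSF
    if (deconv_sigma_px > 0)
      f <- wiener_deconv(f, deconv_sigma_px * upsample_factor, wiener_k)
    out[[i]] <- clamp(f, 0, 1)
  }
  image_stack(out, pixel_size_um = stack$pixel_size_um / upsample_factor,
              frame_interval_s = stack$frame_interval_s,
              provenance = paste0(stack$provenance, "|enhanced"))
}

## Wiener deconvolution with a Gaussian optical transfer function; operates
## in the Fourier domain (the flattened frames are near-uniform at their
## borders, so wrap-around effects are negligible)
wiener_deconv <- function(img, sigma_px, k = 0.01) {
  nr <- nrow(img); nc <- ncol(img)
  mu <- mean(img)
  fr <- c(0:(nr %/% 2), -((ceiling(nr / 2) - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((ceiling(nc / 2) - 1):1)) / nc
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, "+"))
  Fi <- stats::fft(img - mu)
  Re(stats::fft(Fi * H / (H^2 + k), inverse = TRUE)) / (nr * nc) + mu
}

## smooth background field: blockwise upper quantile over pixels outside a
## rough (Otsu) specimen mask, specimen-dominated blocks inpainted from
## their neighbours, then bilinearly resized and smoothed. Excluding the
## specimen matters when it spans several blocks (a gastrulation-stage
## embryo fills most of its field of view): otherwise the "background"
## under the body is the body itself and flattening erases its contrast.
estimate_background <- function(f, block_px = 16, q = 0.8) {
  nr <- nrow(f); nc <- ncol(f)
  rng <- range(f)
  fg <- if (diff(rng) > 1e-8)
    f < EBImage::otsu(f, range = rng) # dark specimen
  else matrix(FALSE, nr, nc)
  if (mean(fg) > 0.6) fg[] <- FALSE # polarity/contrast degenerate; keep all
  br <- max(1L, nr %/% block_px); bc <- max(1L, nc %/% block_px)
  ri <- pmin(((seq_len(nr) - 1L) %/% block_px) + 1L, br)
  ci <- pmin(((seq_len(nc) - 1L) %/% block_px) + 1L, bc)
  bi <- (ci[col(f)] - 1L) * br + ri[row(f)]
  keep <- !fg
  blocks <- rep(NA_real_, br * bc)
  agg <- tapply(f[keep], bi[keep], quantile, probs = q, names = FALSE)
  blocks[as.integer(names(agg))] <- agg
  counts <- tabulate(bi[keep], nbins = br * bc)
  blocks[counts < block_px] <- NA # too few background pixels to trust
  blocks <- matrix(blocks, br, bc)
  ## inpaint specimen-dominated blocks from neighbour means
  while (anyNA(blocks)) {
    nas <- which(is.na(blocks), arr.ind = TRUE)
    filled <- FALSE
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      nb <- blocks[max(1, i - 1):min(br, i + 1),
                   max(1, j - 1):min(bc, j + 1)]
      if (any(!is.na(nb))) {
        blocks[i, j] <- mean(nb, na.rm = TRUE)
        filled <- TRUE
      }
    }
    if (!filled) { blocks[is.na(blocks)] <- median(f[keep]); break }
  }
  bg <- EBImage::resize(blocks, w = nr, h = nc)
  gauss_blur_fft(bg, block_px / 2)
}

## fraction of the local foreground amplitude at which the observed limb of
## a cylinder with half-width r_px crosses its geometric boundary. The
## observation model is a Beer-Lambert attenuation profile passed through
## the full imaging chain: Gaussian PSF, box pixel aperture, and (when the
## enhancement deconvolved) the Wiener restoration filter -- whose residual
## blur at noise-limited frequencies is captured exactly by its transfer
## function H/(H^2 + k).
edge_threshold_frac <- function(r_px, sigma_px, tau_px, aperture_px = 1,
                                deconv_sigma_px = 0, wiener_k = 0.05) {
  du <- 0.02
  u <- seq(-2 * r_px, 2 * r_px - du / 2, by = du)
  n <- length(u)
  thick <- ifelse(abs(u) < r_px, 2 * sqrt(pmax(r_px^2 - u^2, 0)), 0)
  c0 <- 1 - exp(-thick / tau_px)
  fpx <- c(0:(n %/% 2), -((ceiling(n / 2) - 1):1)) / (n * du) # cycles/px
  G <- exp(-2 * pi^2 * sigma_px^2 * fpx^2)
  if (deconv_sigma_px > 0) {
    Hd <- exp(-2 * pi^2 * deconv_sigma_px^2 * fpx^2)
    G <- G * Hd / (Hd^2 + wiener_k)
  }
  sx <- pi * fpx * aperture_px
  G <- G * ifelse(abs(sx) < 1e-9, 1, sin(sx) / sx)
  cb <- Re(stats::fft(stats::fft(c0) * G, inverse = TRUE)) / n
  frac <- cb[which.min(abs(u - r_px))] / quantile(cb, 0.999)
  clamp(frac, 0.1, 0.6)
}

#' Segment a stack into per-frame silhouettes
#'
#' The stack is reduced to specimen-contrast frames (background minus image
#' for a dark specimen) and thresholded with stack-global statistics, which
#' keeps the silhouette boundary consistent across frames (the illumination
#' does not change while the specimen rotates): a pooled Otsu pass detects
#' the specimen core, and the boundary threshold is then placed at the
#' contrast level where a blurred Beer-Lambert limb of the specimen's
#' estimated half-width crosses its geometric edge (computed from a 1D
#' forward model given the PSF width and attenuation length), applied per
#' column relative to the column's pooled amplitude so that faint thin tips
#' are still caught, and floored at `noise_k` background MADs. Each frame's
#' mask is morphologically closed, hole-filled, and reduced to its largest
#' connected component.
#'
#' A per-column confidence (contrast normalized by the stack's foreground
#' amplitude) gates the confident longitudinal extent: the maximal run of
#' columns whose confidence reaches `c_min`. Columns outside the extent
#' (e.g. a faint tail at an unfavourable orientation) impose no carving
#' constraints downstream. Frames with no credible foreground are flagged
#' as failed, never silently zero-filled.
#'
#' Column extents are 1-based closed intervals `[x_lo, x_hi]`.
#'
#' @param stack an (ideally enhanced) [image_stack()].
#' @param polarity `"dark"` if the specimen is darker than background.
#' @param close_radius radius (px) of the morphological closing brush.
#' @param min_area_px minimum credible foreground area, px.
#' @param c_min confidence threshold (fraction of the stack's robust
#'   contrast amplitude) for the confident extent.
#' @param psf_sigma_px width of the acquisition PSF in current pixels
#'   (after any enhancement upsampling).
#' @param attenuation_um optical attenuation length of the specimen, um.
#' @param noise_k noise floor of the boundary threshold, in background MADs.
#' @param aperture_px box aperture of a sensor pixel in current pixels
#'   (equals the enhancement upsample factor on upsampled stacks).
#' @param deconv_sigma_px,wiener_k Wiener deconvolution applied during
#'   enhancement (in current pixels), so the boundary model can account
#'   for the restored edge profile; `deconv_sigma_px = 0` when the stack
#'   was not deconvolved.
#' @return an object of class `silhouette_stack`: logical `masks`
#'   `[rows, cols, T]`, per-frame `centroid` (rows `cy`, `cx`), per-column
#'   `confidence`, `extent` (T x 2), `failed` flags, and slots filled later
#'   by the kinematics stage (`offsets`, `resid`, `axis_row`, `angles_rad`,
#'   `selected`).
#' @export
segment <- function(stack, polarity = c("dark", "bright"),
                    close_radius = 2, min_area_px = 30, c_min = 0.3,
                    psf_sigma_px = 1.2, attenuation_um = 25, noise_k = 3,
                    aperture_px = 1, deconv_sigma_px = 0, wiener_k = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  polarity <- match.arg(polarity)
  d <- dim(stack$frames)
  nT <- d[3]
  masks <- array(FALSE, d)
  conf <- matrix(0, d[2], nT)
  sub_lo <- matrix(NA_real_, d[2], nT)
  sub_hi <- matrix(NA_real_, d[2], nT)
  extent <- matrix(NA_integer_, nT, 2)
  centroid <- matrix(NA_real_, nT, 2, dimnames = list(NULL, c("cy", "cx")))
  failed <- logical(nT)
  brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")

  ## specimen-contrast frames
  X <- array(0, d)
  for (i in seq_len(nT)) {
    f <- stack$frames[, , i]
    x <- if (polarity == "dark") median(f) - f else f - median(f)
    X[, , i] <- x
  }
  ## residual shading correction: a planar fit over background pixels
  ## (vertical+horizontal components; a biased mask boundary on one side
  ## of the body would distort the carved hull anisotropically), then a
  ## low per-column quantile for any remaining column structure
  hi0 <- max(quantile(X, 0.999), 1e-6)
  rough_fg <- X > EBImage::otsu(matrix(clamp(X, 0, hi0), 1), range = c(0, hi0))
  rows_idx <- rep(seq_len(d[1]), times = d[2] * nT)
  cols_idx <- rep(rep(seq_len(d[2]), each = d[1]), times = nT)
  bg_sel <- which(!rough_fg)
  if (length(bg_sel) > 50000L)
    bg_sel <- bg_sel[seq(1, length(bg_sel), length.out = 50000L)]
  fit <- stats::lm.fit(cbind(1, rows_idx[bg_sel], cols_idx[bg_sel]),
                       X[bg_sel])
  plane <- matrix(fit$coefficients[1] +
                    fit$coefficients[2] * rep(seq_len(d[1]), d[2]) +
                    fit$coefficients[3] * rep(seq_len(d[2]), each = d[1]),
                  d[1], d[2])
  for (i in seq_len(nT)) {
    x <- X[, , i] - plane
    x <- sweep(x, 2, apply(x, 2, quantile, probs = 0.15, names = FALSE))
    x[x < 0] <- 0
    X[, , i] <- x
  }

  ## stack-global statistics: core detection, amplitude, noise
  sub <- X[seq(1, length(X), by = max(1L, length(X) %/% 200000L))]
  hi <- quantile(sub, 0.999)
  if (hi <= 0) stopf("no specimen contrast anywhere in the stack")
  thr0 <- EBImage::otsu(matrix(pmin(sub, hi), 1), range = c(0, hi))
  fg0 <- X > thr0
  if (!any(fg0)) stopf("no specimen core detected in the stack")
  stat_sub <- function(a, cond) {
    v <- a[cond]
    if (length(v) > 400000L) v <- v[seq(1, length(v), length.out = 400000L)]
    v
  }
  amp <- quantile(stat_sub(X, fg0), 0.99)
  noise_mad <- stats::mad(stat_sub(X, !fg0))

  ## median core half-width (px) over columns and frames -> edge fraction
  core_rows <- apply(fg0, c(2, 3), sum)
  hw_px <- median(core_rows[core_rows > 0]) / 2
  frac <- edge_threshold_frac(hw_px, psf_sigma_px,
                              attenuation_um / stack$pixel_size_um,
                              aperture_px, deconv_sigma_px, wiener_k)

  ## per-column pooled amplitude (smoothed along columns) so faint thin
  ## tips keep a locally appropriate boundary level; the cap at 1.5x the
  ## raw column amplitude stops bright neighbouring body columns from
  ## inflating the threshold over a faint tip
  row_str <- seq(1, d[1], by = if (d[1] > 64) 2L else 1L)
  frm_str <- seq(1, nT, by = if (nT > 48) 2L else 1L)
  A_raw <- apply(X[row_str, , frm_str, drop = FALSE], 2, quantile,
                 probs = 0.995)
  ks <- 9
  A_col <- as.numeric(stats::filter(c(rep(A_raw[1], ks), A_raw,
                                      rep(A_raw[d[2]], ks)),
                                    rep(1 / (2 * ks + 1), 2 * ks + 1),
                                    sides = 2))[ks + seq_len(d[2])]
  A_col <- pmin(A_col, 1.5 * A_raw)
  ## the absolute floor (4% of the foreground amplitude) matters for very
  ## clean stacks, where the noise MAD alone would let residual shading
  ## structure through in background columns
  thr_col <- pmax(frac * pmin(A_col, amp), noise_k * noise_mad, 0.04 * amp)

  ## weak (hysteresis) detector for sub-resolution tips: the same contrast
  ## smoothed at the feature scale has ~3x the tip SNR, so a lower floor is
  ## safe; weak evidence only counts where it connects to the strong mask
  Xs <- array(0, d)
  for (i in seq_len(nT)) Xs[, , i] <- gauss_blur_fft(X[, , i], 1.5)
  fg0s <- Xs > thr0
  mad_s <- stats::mad(stat_sub(Xs, !fg0s))
  A_raw_s <- apply(Xs[row_str, , frm_str, drop = FALSE], 2, quantile,
                   probs = 0.995)
  A_col_s <- as.numeric(stats::filter(c(rep(A_raw_s[1], ks), A_raw_s,
                                        rep(A_raw_s[d[2]], ks)),
                                      rep(1 / (2 * ks + 1), 2 * ks + 1),
                                      sides = 2))[ks + seq_len(d[2])]
  A_col_s <- pmin(A_col_s, 1.5 * A_raw_s)
  thr_weak <- pmax(frac * pmin(A_col_s, amp), 2.5 * mad_s, 0.10 * amp)

  for (i in seq_len(nT)) {
    x <- X[, , i]
    m <- sweep(x, 2, thr_col, ">")
    if (sum(m) >= min_area_px) {
      m <- EBImage::fillHull(EBImage::closing(m, brush))
      lab <- EBImage::bwlabel(m)
      if (max(lab) >= 1) {
        sizes <- tabulate(lab[lab > 0])
        m <- lab == which.max(sizes)
      }
    }
    if (sum(m) < min_area_px) { failed[i] <- TRUE; next }
    ## hysteresis: weak-mask component connected to the strong mask; only
    ## columns where the strong detector saw nothing adopt weak bounds
    xs <- Xs[, , i]
    mw <- sweep(xs, 2, thr_weak, ">")
    labw <- EBImage::bwlabel(mw)
    touched <- setdiff(unique(labw[m]), 0L)
    if (length(touched)) {
      mw <- array(labw %in% touched, dim(labw))
      strong_cols <- which(colSums(m) > 0)
      reach <- ceiling(3 * hw_px)
      add_cols <- which(colSums(m) == 0 & colSums(mw) > 0)
      add_cols <- add_cols[add_cols >= min(strong_cols) - reach &
                             add_cols <= max(strong_cols) + reach]
      strong_span <- colSums(m)
      for (jc in add_cols) {
        rows_w <- which(mw[, jc])
        if (length(rows_w) > 4 * hw_px) next
        ## a tapering tip never grows beyond its nearest detected column;
        ## cap the (smoothing-widened) weak span accordingly, centred on
        ## the weak evidence
        js <- strong_cols[which.min(abs(strong_cols - jc))]
        cap <- max(2L, strong_span[js])
        if (length(rows_w) > cap) {
          ctr <- round(stats::weighted.mean(rows_w, xs[rows_w, jc]))
          rows_w <- rows_w[rows_w >= ctr - cap %/% 2 &
                             rows_w <= ctr + cap %/% 2]
          if (!length(rows_w)) next
        }
        m[rows_w[1]:rows_w[length(rows_w)], jc] <- TRUE
      }
    }
    m <- regularize_mask(m)
    masks[, , i] <- m
    sub <- subpixel_bounds(x, m, thr_col, xs, thr_weak, frac)
    sub_lo[, i] <- sub$lo
    sub_hi[, i] <- sub$hi
    idx <- which(m, arr.ind = TRUE)
    centroid[i, ] <- c(mean(idx[, 1]), mean(idx[, 2]))
    ## per-column confidence: robust specimen contrast of the mask pixels
    ## in the column (on the smoothed field, whose noise floor is lower),
    ## relative to the best contrast the stack ever shows for that column
    ## -- so an intrinsically thin (but well seen) tip is confident, while
    ## a column faded in this particular frame is not
    cs <- rep(0, d[2])
    colq <- tapply(xs[m], idx[, 2], quantile, probs = 0.9, names = FALSE)
    jj <- as.integer(names(colq))
    cs[jj] <- colq / pmax(A_raw_s[jj], 2.5 * mad_s)
    conf[, i] <- clamp(cs, 0, 1)
    run <- longest_run(conf[, i] >= c_min)
    if (is.null(run)) { failed[i] <- TRUE; masks[, , i] <- FALSE; next }
    extent[i, ] <- run
  }

  structure(list(masks = masks, centroid = centroid, confidence = conf,
                 sub_lo = sub_lo, sub_hi = sub_hi,
                 extent = extent, failed = failed,
                 offsets = matrix(0L, nT, 2,
                                  dimnames = list(NULL, c("dy", "dx"))),
                 resid = matrix(0, nT, 2,
                                dimnames = list(NULL, c("ry", "rx"))),
                 axis_row = NA_real_, angles_rad = rep(NA_real_, nT),
                 selected = rep(FALSE, nT),
                 pixel_size_um = stack$pixel_size_um,
                 period_frames = NA_real_),
            class = "silhouette_stack")
}

#' @export
print.silhouette_stack <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf(
    "<silhouette_stack> %d frames (%d failed), %d x %d px, %.3g um/px\n",
    d[3], sum(x$failed), d[1], d[2], x$pixel_size_um))
  if (any(x$selected))
    cat(sprintf("  %d frames angle-stamped over one period of %.2f frames\n",
                sum(x$selected), x$period_frames))
  invisible(x)
}

## sub-pixel silhouette boundary: within each mask column, the vertical
## position where the contrast profile crosses the column threshold,
## located by linear interpolation between the boundary pixel and its
## background neighbour. Continuous bounds remove the frame-to-frame
## quantization jitter that would otherwise erode the carved hull (strip
## intersection keeps the narrowest estimate seen in any frame).
subpixel_bounds <- function(x, m, thr_col, x_weak = NULL, thr_weak = NULL,
                            frac = NULL) {
  nc <- ncol(m); nr <- nrow(m)
  lo <- rep(NA_real_, nc); hi <- lo
  for (j in which(colSums(m) > 0)) {
    rows <- which(m[, j])
    a <- rows[1]; b <- rows[length(rows)]
    thr <- thr_col[j]
    xj <- x
    if (!is.null(x_weak) && x[a, j] <= thr && x[b, j] <= thr) {
      ## column owes its mask to the weak (smoothed) detector
      xj <- x_weak
      thr <- thr_weak[j]
    }
    ## the boundary level scales with the frame-local column amplitude: a
    ## contrast fade multiplies the whole profile, so the geometric
    ## boundary stays at the same *fraction* of the local peak
    if (!is.null(frac)) {
      peak <- max(xj[rows, j])
      thr <- min(thr, frac * peak)
    }
    lo[j] <- if (a > 1 && xj[a, j] > thr && xj[a - 1, j] < xj[a, j])
      a - clamp((xj[a, j] - thr) / (xj[a, j] - xj[a - 1, j]), 0, 1)
    else a - 0.5
    hi[j] <- if (b < nr && xj[b, j] > thr && xj[b + 1, j] < xj[b, j])
      b + clamp((xj[b, j] - thr) / (xj[b, j] - xj[b + 1, j]), 0, 1)
    else b + 0.5
  }
  list(lo = lo, hi = hi)
}

## boundary regularization: the body outline varies smoothly along the
## axis, so a short running median over the per-column top/bottom rows
## suppresses single-pixel boundary noise (which would otherwise erode the
## carved hull, since strip intersection keeps the narrowest estimate seen
## in any frame); columns are rebuilt as vertical spans, the convention the
## carver uses anyway
regularize_mask <- function(m) {
  sup <- which(colSums(m) > 0)
  if (length(sup) < 7 || any(diff(sup) != 1L)) return(m)
  rmin <- vapply(sup, function(c) min(which(m[, c])), numeric(1))
  rmax <- vapply(sup, function(c) max(which(m[, c])), numeric(1))
  rmin_s <- clamp(round(stats::runmed(rmin, 5, endrule = "keep")),
                  pmax(rmin - 1, 1), rmin + 1)
  rmax_s <- clamp(round(stats::runmed(rmax, 5, endrule = "keep")),
                  rmax - 1, pmin(rmax + 1, nrow(m)))
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_along(sup))
    out[rmin_s[k]:rmax_s[k], sup[k]] <- TRUE
  out
}

#' Write silhouette masks as a binary multi-page TIFF
#' @param sils a `silhouette_stack`.
#' @param path output file.
#' @export
write_masks <- function(sils, path) {
  write_stack(sils$masks * 1, path, bits_per_sample = 8)
}
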