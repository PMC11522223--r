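## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## clamp to [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

## longest run of TRUE in a logical vector; returns c(start, end) (1-based,
## closed) or NULL when no TRUE present
longest_run <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(starts[best], ends[best])
}

## separable 3D Gaussian smoothing of a numeric array (reflecting the kernel
## at zero-padded borders); sigma in voxels
gauss3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(a)
  for (ax in 1:3) {
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(d[ax]) + off
      keep <- src >= 1L & src <= d[ax]
      idx_dst <- which(keep)
      idx_src <- src[keep]
      if (ax == 1) out[idx_dst, , ] <- out[idx_dst, , ] + k[j] * a[idx_src, , ]
      else if (ax == 2) out[, idx_dst, ] <- out[, idx_dst, ] + k[j] * a[, idx_src, ]
      else out[, , idx_dst] <- out[, , idx_dst] + k[j] * a[, , idx_src]
    }
    a <- out
  }
  a
}

## integer-pixel translation of a matrix, padding with `fill`
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  r_src <- seq_len(nrow(m)) - dr
  c_src <- seq_len(ncol(m)) - dc
  rk <- r_src >= 1 & r_src <= nrow(m)
  ck <- c_src >= 1 & c_src <= ncol(m)
  out[which(rk), which(ck)] <- m[r_src[rk], c_src[ck]]
  out
}

## angular distance in degrees, in [0, 180]
ang_dist_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

## FFT-based Gaussian blur with replicate-equivalent behaviour for images
## whose borders are near-uniform (all uses in this package); much faster
## than spatial convolution for the kernel widths involved
gauss_blur_fft <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  mu <- mean(img)
  fr <- c(0:(nr %/% 2), -((ceiling(nr / 2) - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((ceiling(nc / 2) - 1):1)) / nc
  H <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, "+"))
  Re(stats::fft(stats::fft(img - mu) * H, inverse = TRUE)) / (nr * nc) + mu
}
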