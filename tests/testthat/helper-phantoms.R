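# Shared fixtures, generated in code and memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# a small bent worm acquisition (240 um worm at 2 um/px, 24-frame period)
small_worm_conditions <- function(seed = 1, noise = 0.02, tail_fade = 0,
                                  drift = c(0, 0), drift_walk = 0) {
  list(spec = phantom_spec("worm", length_um = 240, max_radius_um = 16,
                           taper = 0.15, cap_frac = 0.15,
                           bend_amplitude_um = 12, bend_wavelength_um = 220,
                           bend_phase = 0.8, rng_seed = seed),
       rspec = render_spec(n_frames = 36, period_frames = 24,
                           pixel_size_um = 2, dim = c(48, 160),
                           noise_sigma = noise, tail_fade = tail_fade,
                           drift_px_per_frame = drift,
                           drift_walk_sd = drift_walk, seed = seed))
}

small_embryo_conditions <- function(seed = 1, noise = 0.02) {
  list(spec = phantom_spec("embryo", semi_axes_um = c(25, 15, 15),
                           bump_amplitude = 0.05, rng_seed = seed),
       rspec = render_spec(n_frames = 36, period_frames = 24,
                           pixel_size_um = 1, dim = c(48, 96),
                           noise_sigma = noise, seed = seed))
}

# rendered + segmented + angle-stamped small worm, shared across test files
small_worm_fixture <- function() {
  memo("small_worm", {
    cond <- small_worm_conditions()
    ph <- build_phantom(cond$spec, 1)
    rnd <- render_stack(ph, cond$rspec)
    enh <- enhance(rnd$stack)
    sils <- segment(enh)
    est <- estimate_period(enh)
    sils <- align_frames(sils, est$period_frames)
    sils <- assign_angles(est, sils)
    vol <- carve_slicewise(sils)
    list(cond = cond, ph = ph, rnd = rnd, enh = enh, sils = sils,
         est = est, vol = vol)
  })
}

# a directly voxelized sphere as a voxel_volume (no pipeline involved)
sphere_volume <- function(r = 20, vox = 1) {
  m <- ceiling(r / vox) + 2
  co <- (-m:m) * vox
  g <- array(FALSE, c(length(co), length(co), length(co)))
  for (i in seq_along(co)) g[i, , ] <- outer(co^2, co^2, "+") <= r^2 - co[i]^2
  structure(list(grid = g, voxel_um = vox, cols = seq_along(co), y_um = co,
                 z_um = co, axis_row = m + 1, img_dim = c(length(co), length(co)),
                 pixel_size_um = vox), class = "voxel_volume")
}

# wrap a phantom's true occupancy grid as a voxel_volume (tests the
# morphometry operators against exact geometry, independent of carving)
vol_from_phantom <- function(ph) {
  ny <- length(ph$y_um)
  stopifnot(abs(ph$y_um[(ny + 1) / 2]) < 1e-9) # centred cross-section grid
  structure(list(grid = ph$grid, voxel_um = ph$voxel_um,
                 cols = seq_along(ph$x_um), y_um = ph$y_um, z_um = ph$z_um,
                 axis_row = (ny + 1) / 2,
                 img_dim = c(ny, length(ph$x_um)),
                 pixel_size_um = ph$voxel_um), class = "voxel_volume")
}

# an ideal silhouette stack built from analytic sub-pixel bounds:
# `half_height_px(col)` gives the silhouette half-height per column (NA for
# empty columns), identical at N angles uniform in [0, pi) unless
# `per_angle` supplies a function(theta) -> half-height vector
ideal_sils <- function(N, half_height_px, ncol = 64, nrow = 64,
                       pixel_size_um = 1) {
  axis_row <- (nrow + 1) / 2
  theta <- pi * (0:(N - 1)) / N
  hh <- if (is.function(half_height_px)) half_height_px else
    function(th) half_height_px
  masks <- array(FALSE, c(nrow, ncol, N))
  sub_lo <- matrix(NA_real_, ncol, N)
  sub_hi <- matrix(NA_real_, ncol, N)
  extent <- matrix(NA_integer_, N, 2)
  centroid <- matrix(NA_real_, N, 2, dimnames = list(NULL, c("cy", "cx")))
  for (i in seq_len(N)) {
    h <- hh(theta[i])
    sup <- which(!is.na(h) & h > 0)
    sub_lo[sup, i] <- axis_row - h[sup]
    sub_hi[sup, i] <- axis_row + h[sup]
    for (j in sup) {
      r0 <- max(1L, ceiling(axis_row - h[j]))
      r1 <- min(nrow, floor(axis_row + h[j]))
      if (r0 <= r1) masks[r0:r1, j, i] <- TRUE
    }
    extent[i, ] <- range(sup)
    centroid[i, ] <- c(axis_row, mean(sup))
  }
  structure(list(masks = masks, centroid = centroid,
                 confidence = matrix(1, ncol, N),
                 sub_lo = sub_lo, sub_hi = sub_hi,
                 extent = extent, failed = rep(FALSE, N),
                 offsets = matrix(0L, N, 2, dimnames = list(NULL, c("dy", "dx"))),
                 resid = matrix(0, N, 2, dimnames = list(NULL, c("ry", "rx"))),
                 axis_row = axis_row, angles_rad = theta,
                 selected = rep(TRUE, N), pixel_size_um = pixel_size_um,
                 period_frames = 2 * N), class = "silhouette_stack")
}

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)
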