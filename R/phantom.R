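## phantom module: parametric 3D specimens with analytic/oracle ground truth,
## plus a renderer that turns them into rotation image stacks. Stands in for
## the robotic rotation rig and the microscope.

#' Define a parametric phantom specimen
#'
#' Phantoms emulate the specimens the rotation rig handles: rod-like adult
#' worms (maximum diameter around 50 um, body length around 1 mm) and oval
#' embryos (around 30 um diameter by 50 um length), plus simple calibration
#' solids (sphere, cylinder, ellipsoid) with closed-form metrics.
#'
#' The specimen lives in its co-rotating frame: x runs along the rotation
#' axis, (y, z) span the cross-section plane. Worms are tubes around a
#' centerline that may bend within the co-rotating y plane; their radius
#' profile combines cosine end caps (`cap_frac` of the length each) with a
#' mid-body taper `(4 s (1-s))^taper`. Embryos/ellipsoids have semi-axes
#' `semi_axes_um = c(a, b, c)` (a along x) and an optional smooth surface
#' bump field of relative amplitude `bump_amplitude`. Internal "landmark"
#' blobs of extra optical density (seeded) break rotational and mirror
#' symmetry the way organelles and gut granules do in real brightfield
#' frames; the period estimator relies on such internal texture.
#'
#' @param kind one of `"worm"`, `"embryo"`, `"cylinder"`, `"sphere"`,
#'   `"ellipsoid"`.
#' @param length_um body length (worm/cylinder) or sphere diameter, um.
#' @param max_radius_um maximum body radius, um.
#' @param taper mid-body taper exponent (worm), dimensionless, >= 0.
#' @param cap_frac fraction of the length occupied by each cosine end cap.
#' @param bend_amplitude_um,bend_wavelength_um,bend_phase sinusoidal
#'   centerline bend in the co-rotating y plane.
#' @param semi_axes_um semi-axes `c(a, b, c)` for embryo/ellipsoid, um.
#' @param bump_amplitude relative amplitude of the embryo surface bumps.
#' @param bump_freq angular frequency of the dominant bump component.
#' @param n_landmarks number of internal density blobs.
#' @param landmark_strength relative optical density of the blobs.
#' @param rng_seed integer seed for the landmark/bump phases.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("worm", "embryo", "cylinder", "sphere", "ellipsoid"),
                         length_um = NULL, max_radius_um = NULL,
                         taper = 0.15, cap_frac = 0.12,
                         bend_amplitude_um = 0, bend_wavelength_um = NULL,
                         bend_phase = 0,
                         semi_axes_um = NULL,
                         bump_amplitude = 0, bump_freq = 3,
                         n_landmarks = NULL, landmark_strength = 0.8,
                         rng_seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "worm") {
    length_um <- length_um %||% 1000
    max_radius_um <- max_radius_um %||% 25
    n_landmarks <- n_landmarks %||% 8L
  } else if (kind == "embryo") {
    semi_axes_um <- semi_axes_um %||% c(25, 15, 15)
    if (bump_amplitude == 0) bump_amplitude <- 0.05
    n_landmarks <- n_landmarks %||% 3L
  } else if (kind == "ellipsoid") {
    semi_axes_um <- semi_axes_um %||% c(25, 15, 15)
    n_landmarks <- n_landmarks %||% 0L
  } else if (kind == "sphere") {
    max_radius_um <- max_radius_um %||% 25
    length_um <- 2 * max_radius_um
    n_landmarks <- n_landmarks %||% 0L
  } else { # cylinder
    length_um <- length_um %||% 1000
    max_radius_um <- max_radius_um %||% 25
    n_landmarks <- n_landmarks %||% 0L
  }

  if (kind %in% c("embryo", "ellipsoid")) {
    if (any(semi_axes_um <= 0)) stopf("semi-axes must all be positive")
    length_um <- 2 * semi_axes_um[1]
    max_radius_um <- max(semi_axes_um[2:3])
  }
  if (is.null(length_um) || length_um <= 0) stopf("length_um must be > 0")
  if (is.null(max_radius_um) || max_radius_um <= 0)
    stopf("max_radius_um must be > 0")
  if (kind == "worm" && 2 * max_radius_um > length_um)
    stopf("a worm must satisfy 2*max_radius_um <= length_um")
  if (cap_frac <= 0 || cap_frac > 0.5) stopf("cap_frac must be in (0, 0.5]")
  if (kind == "worm") bend_wavelength_um <- bend_wavelength_um %||% (0.9 * length_um)

  structure(list(
    kind = kind, length_um = length_um, max_radius_um = max_radius_um,
    taper = taper, cap_frac = cap_frac,
    bend_amplitude_um = bend_amplitude_um,
    bend_wavelength_um = bend_wavelength_um, bend_phase = bend_phase,
    semi_axes_um = semi_axes_um,
    bump_amplitude = bump_amplitude, bump_freq = bump_freq,
    n_landmarks = as.integer(n_landmarks),
    landmark_strength = landmark_strength,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s: length %.1f um, max radius %.1f um, seed %d\n",
              x$kind, x$length_um, x$max_radius_um, x$rng_seed))
  invisible(x)
}

## radius profile of a worm along normalized arc s in [0,1]
worm_radius <- function(spec, s) {
  r <- rep(0, length(s))
  inside <- s >= 0 & s <= 1
  si <- s[inside]
  ramp <- rep(1, length(si))
  lo <- si < spec$cap_frac
  hi <- si > 1 - spec$cap_frac
  ramp[lo] <- sin(pi / 2 * si[lo] / spec$cap_frac)
  ramp[hi] <- sin(pi / 2 * (1 - si[hi]) / spec$cap_frac)
  tap <- (4 * pmax(si * (1 - si), 0))^spec$taper
  r[inside] <- spec$max_radius_um * ramp * tap
  r
}

## centerline y offset (co-rotating plane) of a worm at normalized arc s;
## mean-centred so the bend does not displace the centroid
worm_bend <- function(spec, s) {
  if (spec$bend_amplitude_um == 0) return(rep(0, length(s)))
  f <- function(u) sin(2 * pi * u * spec$length_um / spec$bend_wavelength_um +
                         spec$bend_phase)
  sg <- seq(0, 1, length.out = 2048)
  spec$bend_amplitude_um * (f(s) - mean(f(sg)))
}

## embryo/ellipsoid cross-section radius rho(x, psi) including surface bumps;
## x relative to the centre, psi the angle in the (y, z) plane
embryo_radius <- function(spec, x, psi) {
  a <- spec$semi_axes_um[1]; b <- spec$semi_axes_um[2]; c3 <- spec$semi_axes_um[3]
  t <- pmax(1 - (x / a)^2, 0)
  base <- sqrt(t / (cos(psi)^2 / b^2 + sin(psi)^2 / c3^2))
  if (spec$bump_amplitude > 0) {
    ph <- bump_phases(spec)
    s <- (x / a + 1) / 2
    w <- sin(pi * pmin(pmax(s, 0), 1))
    g <- 0.7 * cos(spec$bump_freq * psi + ph[1]) +
      0.3 * cos((spec$bump_freq + 1) * psi + ph[2])
    base <- base * (1 + spec$bump_amplitude * w * g)
  }
  base
}

bump_phases <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed + 7L)
  runif(2, 0, 2 * pi)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Voxelize a phantom and compute its ground truth
#'
#' Builds the occupancy grid of the specimen in its co-rotating frame at the
#' requested voxel pitch, an optical-density field (1 inside the body plus
#' seeded internal landmark blobs), and the ground-truth record: the five
#' morphometric metrics evaluated from the continuous parametric definition
#' (closed forms where they exist, otherwise fine numerical quadrature of the
#' parametric surface/solid) and a parametric surface mesh.
#'
#' @param spec a [phantom_spec()].
#' @param voxel_um voxel pitch, um; must satisfy `voxel_um <= max_radius/4`
#'   for adequate sampling of the cross-section.
#' @return a list of class `phantom` with elements `grid` (logical 3D array),
#'   `density` (numeric 3D array), coordinate vectors `x_um`, `y_um`, `z_um`,
#'   `voxel_um`, `spec` and `gt` (list with `surface_area_um2`, `volume_um3`,
#'   `length_um`, `max_width_um`, `ratio`, `max_width_pos`, `mesh`).
#' @export
build_phantom <- function(spec, voxel_um) {
  stopifnot(inherits(spec, "phantom_spec"))
  r_ref <- if (spec$kind %in% c("embryo", "ellipsoid"))
    min(spec$semi_axes_um[2:3]) else spec$max_radius_um
  if (voxel_um > r_ref / 4 + 1e-9)
    stopf("voxel_um = %g too coarse: need voxel_um <= %g (max radius / 4)",
          voxel_um, r_ref / 4)

  L <- spec$length_um
  if (spec$kind %in% c("worm", "cylinder")) {
    s_of <- function(x) x / L
    bend <- function(x) worm_bend(spec, s_of(x))
    rad <- function(x) {
      if (spec$kind == "worm") worm_radius(spec, s_of(x))
      else ifelse(x >= 0 & x <= L, spec$max_radius_um, 0)
    }
    x_um <- seq(voxel_um / 2, L - voxel_um / 2, by = voxel_um)
    ymax <- max(abs(bend(x_um))) + spec$max_radius_um + 2 * voxel_um
    m <- ceiling(ymax / voxel_um)
    y_um <- (-m:m) * voxel_um
    z_m <- ceiling((spec$max_radius_um + 2 * voxel_um) / voxel_um)
    z_um <- (-z_m:z_m) * voxel_um
    grid <- array(FALSE, c(length(x_um), length(y_um), length(z_um)))
    Z2 <- matrix(rep(z_um^2, each = length(y_um)), length(y_um))
    yc <- bend(x_um); rr <- rad(x_um)
    for (i in seq_along(x_um)) {
      if (rr[i] <= 0) next
      D2 <- (y_um - yc[i])^2
      grid[i, , ] <- outer(D2, z_um^2, "+") <= rr[i]^2
    }
  } else if (spec$kind == "sphere") {
    r <- spec$max_radius_um
    m <- ceiling((r + 2 * voxel_um) / voxel_um)
    x_um <- (-m:m) * voxel_um; y_um <- x_um; z_um <- x_um
    grid <- array(FALSE, c(length(x_um), length(y_um), length(z_um)))
    for (i in seq_along(x_um))
      grid[i, , ] <- outer(y_um^2, z_um^2, "+") <= r^2 - x_um[i]^2
  } else { # embryo / ellipsoid
    a <- spec$semi_axes_um[1]
    rmax <- spec$max_radius_um * (1 + spec$bump_amplitude)
    mx <- ceiling((a + 2 * voxel_um) / voxel_um)
    my <- ceiling((rmax + 2 * voxel_um) / voxel_um)
    x_um <- (-mx:mx) * voxel_um
    y_um <- (-my:my) * voxel_um; z_um <- y_um
    PSI <- outer(y_um, z_um, function(y, z) atan2(z, y))
    RHO <- sqrt(outer(y_um^2, z_um^2, "+"))
    grid <- array(FALSE, c(length(x_um), length(y_um), length(z_um)))
    for (i in seq_along(x_um)) {
      if (abs(x_um[i]) >= a) next
      grid[i, , ] <- RHO <= embryo_radius(spec, x_um[i], PSI)
    }
  }

  dim3 <- dim(grid)
  grid <- array(.largest_component(grid, dim3), dim3)
  if (!any(grid)) stopf("degenerate phantom: empty occupancy grid")

  density <- array(1, dim3)
  if (spec$n_landmarks > 0) {
    occ_idx <- which(grid)
    coords <- arrayInd(occ_idx, dim3)
    pts_um <- cbind(x_um[coords[, 1]], y_um[coords[, 2]], z_um[coords[, 3]])
    lm <- with_seed(spec$rng_seed, {
      pick <- sample(nrow(pts_um), spec$n_landmarks, replace = FALSE)
      list(centre = pts_um[pick, , drop = FALSE],
           radius = runif(spec$n_landmarks, 0.08, 0.2) * 2 * spec$max_radius_um,
           amp = runif(spec$n_landmarks, 0.5, 1) * spec$landmark_strength)
    })
    dens_occ <- rep(1, length(occ_idx))
    for (j in seq_len(spec$n_landmarks)) {
      d2 <- (pts_um[, 1] - lm$centre[j, 1])^2 +
        (pts_um[, 2] - lm$centre[j, 2])^2 +
        (pts_um[, 3] - lm$centre[j, 3])^2
      dens_occ <- dens_occ + lm$amp[j] * exp(-d2 / (2 * lm$radius[j]^2))
    }
    density[occ_idx] <- dens_occ
  }
  density[!grid] <- 0

  structure(list(grid = grid, density = density,
                 x_um = x_um, y_um = y_um, z_um = z_um,
                 voxel_um = voxel_um, spec = spec,
                 gt = phantom_ground_truth(spec)),
            class = "phantom")
}

#' Ground-truth metrics of a phantom from its continuous definition
#'
#' Closed forms for spheres, cylinders and plain ellipsoids; fine numerical
#' quadrature of the parametric surface/solid for worms and bumped embryos.
#'
#' @param spec a [phantom_spec()].
#' @param n_s,n_psi quadrature resolution along the axis and around it.
#' @return list with the five metrics, the arc position of the maximum
#'   width (`max_width_pos`, fraction of length), and a parametric
#'   `surface_mesh` ground-truth mesh.
#' @export
phantom_ground_truth <- function(spec, n_s = 4000, n_psi = 256) {
  L <- spec$length_um
  if (spec$kind == "sphere") {
    r <- spec$max_radius_um
    gt <- list(surface_area_um2 = 4 * pi * r^2,
               volume_um3 = 4 / 3 * pi * r^3,
               length_um = 2 * r, max_width_um = 2 * r, max_width_pos = 0.5)
  } else if (spec$kind == "cylinder") {
    r <- spec$max_radius_um
    gt <- list(surface_area_um2 = 2 * pi * r * L + 2 * pi * r^2,
               volume_um3 = pi * r^2 * L,
               length_um = L, max_width_um = 2 * r, max_width_pos = 0.5)
  } else if (spec$kind %in% c("embryo", "ellipsoid") && spec$bump_amplitude == 0) {
    ax <- spec$semi_axes_um
    p <- 1.6075 # Thomsen approximation for the ellipsoid surface
    area <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                         ax[2]^p * ax[3]^p) / 3)^(1 / p)
    gt <- list(surface_area_um2 = area,
               volume_um3 = 4 / 3 * pi * prod(ax),
               length_um = 2 * ax[1], max_width_um = 2 * max(ax[2:3]),
               max_width_pos = 0.5)
  } else if (spec$kind %in% c("embryo", "ellipsoid")) {
    a <- spec$semi_axes_um[1]
    xg <- seq(-a, a, length.out = n_s + 1)
    xm <- (head(xg, -1) + tail(xg, -1)) / 2
    dx <- diff(xg)[1]
    psi <- seq(0, 2 * pi, length.out = n_psi + 1)[-(n_psi + 1)]
    dpsi <- 2 * pi / n_psi
    RHO <- outer(xm, psi, function(x, p) embryo_radius(spec, x, p))
    vol <- sum(RHO^2) / 2 * dpsi * dx
    ## area by central differences of the parametric surface
    RHO_x <- (rbind(RHO[2:nrow(RHO), ], RHO[nrow(RHO), ]) -
                rbind(RHO[1, ], RHO[1:(nrow(RHO) - 1), ])) /
      rbind(matrix(dx, 1, n_psi), matrix(2 * dx, nrow(RHO) - 2, n_psi),
            matrix(dx, 1, n_psi))
    RHO_p <- (RHO[, c(2:n_psi, 1)] - RHO[, c(n_psi, 1:(n_psi - 1))]) / (2 * dpsi)
    integ <- sqrt(RHO^2 * RHO_x^2 + RHO_p^2 + RHO^2)
    area <- sum(integ) * dpsi * dx
    wid <- vapply(seq_along(xm), function(i) {
      pts <- cbind(RHO[i, ] * cos(psi), RHO[i, ] * sin(psi))
      max_feret(pts)
    }, numeric(1))
    gt <- list(surface_area_um2 = area, volume_um3 = vol,
               length_um = 2 * a, max_width_um = max(wid),
               max_width_pos = (xm[which.max(wid)] + a) / (2 * a))
  } else { # worm
    xg <- seq(0, L, length.out = n_s + 1)
    xm <- (head(xg, -1) + tail(xg, -1)) / 2
    dx <- diff(xg)[1]
    r <- worm_radius(spec, xm / L)
    yc <- worm_bend(spec, xm / L)
    dr <- c(diff(r) / dx, 0); dr <- (dr + c(0, head(dr, -1))) / 2
    dy <- c(diff(yc) / dx, 0); dy <- (dy + c(0, head(dy, -1))) / 2
    vol <- sum(pi * r^2) * dx
    len <- sum(sqrt(1 + dy^2)) * dx
    psi <- seq(0, 2 * pi, length.out = n_psi + 1)[-(n_psi + 1)]
    dpsi <- 2 * pi / n_psi
    ## |p_x x p_psi| = r * sqrt((yc' cos(psi) + r')^2 + 1)
    integ <- r * sqrt(outer(dy, cos(psi))^2 +
                        2 * outer(dy, cos(psi)) * dr + dr^2 + 1)
    area <- sum(integ) * dpsi * dx
    i_star <- which.max(r)
    gt <- list(surface_area_um2 = area, volume_um3 = vol, length_um = len,
               max_width_um = worm_section_feret(spec, xm[i_star]),
               max_width_pos = xm[i_star] / L)
  }
  gt$ratio <- gt$length_um / gt$max_width_um
  gt$mesh <- phantom_mesh(spec)
  gt
}

## maximal Feret diameter of a planar point set
max_feret <- function(pts) {
  if (nrow(pts) < 2) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  max(dist(hp))
}

## Feret diameter of the worm solid cut by the plane normal to the local
## centerline tangent at axial position x0 (numerical, from the continuous
## definition)
worm_section_feret <- function(spec, x0) {
  L <- spec$length_um
  eps <- 1e-4 * L
  m <- (worm_bend(spec, (x0 + eps) / L) - worm_bend(spec, (x0 - eps) / L)) /
    (2 * eps)
  r0 <- worm_radius(spec, x0 / L)
  if (abs(m) < 1e-9) return(2 * r0)
  y0 <- worm_bend(spec, x0 / L)
  ## plane: (x - x0) + m (y - y0) = 0; sample x, y follows, z free
  xs <- seq(x0 - 2 * abs(m) * r0 - eps, x0 + 2 * abs(m) * r0 + eps,
            length.out = 801)
  ys <- y0 - (xs - x0) / m
  yc <- worm_bend(spec, xs / L); rr <- worm_radius(spec, xs / L)
  h2 <- rr^2 - (ys - yc)^2
  ok <- h2 > 0
  if (!any(ok)) return(2 * r0)
  zs <- sqrt(h2[ok])
  p3 <- rbind(cbind(xs[ok], ys[ok], zs), cbind(xs[ok], ys[ok], -zs))
  e1 <- c(-m, 1, 0) / sqrt(1 + m^2); e2 <- c(0, 0, 1)
  rel <- sweep(p3, 2, c(x0, y0, 0))
  max_feret(cbind(rel %*% e1, rel %*% e2))
}

## parametric ground-truth surface mesh (triangulated (x, psi) grid with
## pole fans); vertices in um, co-rotating frame, centred like the grid
phantom_mesh <- function(spec, n_x = 160, n_psi = 48) {
  L <- spec$length_um
  psi <- seq(0, 2 * pi, length.out = n_psi + 1)[-(n_psi + 1)]
  if (spec$kind %in% c("embryo", "ellipsoid", "sphere")) {
    a <- if (spec$kind == "sphere") spec$max_radius_um else spec$semi_axes_um[1]
    xs <- a * cos(seq(pi - 1e-3, 1e-3, length.out = n_x))
    rho <- function(x, p) {
      if (spec$kind == "sphere") sqrt(pmax(spec$max_radius_um^2 - x^2, 0))
      else embryo_radius(spec, x, p)
    }
    poles <- c(-a, a)
    ring_y <- function(x) rho(x, psi) * cos(psi)
    ring_z <- function(x) rho(x, psi) * sin(psi)
    centre_y <- function(x) 0
  } else {
    xs <- seq(L * 1e-4, L * (1 - 1e-4), length.out = n_x)
    poles <- c(0, L)
    ring_y <- function(x) worm_bend(spec, x / L) +
      worm_radius(spec, x / L) * cos(psi)
    ring_z <- function(x) worm_radius(spec, x / L) * sin(psi)
    centre_y <- function(x) worm_bend(spec, x / L)
  }
  nv <- n_x * n_psi
  V <- matrix(0, nv + 2, 3)
  for (i in seq_len(n_x)) {
    idx <- (i - 1) * n_psi + seq_len(n_psi)
    V[idx, 1] <- xs[i]; V[idx, 2] <- ring_y(xs[i]); V[idx, 3] <- ring_z(xs[i])
  }
  V[nv + 1, ] <- c(poles[1], centre_y(poles[1] + 1e-6), 0)
  V[nv + 2, ] <- c(poles[2], centre_y(poles[2] - 1e-6), 0)
  F <- list()
  for (i in seq_len(n_x - 1)) {
    a0 <- (i - 1) * n_psi; a1 <- i * n_psi
    j2 <- c(2:n_psi, 1)
    F[[i]] <- rbind(cbind(a0 + seq_len(n_psi), a1 + seq_len(n_psi), a0 + j2),
                    cbind(a0 + j2, a1 + seq_len(n_psi), a1 + j2))
  }
  j2 <- c(2:n_psi, 1)
  F[[n_x]] <- cbind(nv + 1, seq_len(n_psi), j2)
  F[[n_x + 1]] <- cbind(nv + 2, (n_x - 1) * n_psi + j2,
                        (n_x - 1) * n_psi + seq_len(n_psi))
  mesh <- surface_mesh(V, do.call(rbind, F))
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Define rendering/acquisition parameters for a phantom stack
#'
#' Emulates widefield brightfield acquisition of the rotating specimen:
#' orthographic projection along the optical axis, uniform rotation with a
#' possibly non-integer frame period, in-plane drift, Gaussian PSF blur, a
#' smooth background shading field, additive Gaussian noise, and (worms
#' only) an orientation-dependent low-contrast tail.
#'
#' @param n_frames number of frames; must be >= `period_frames`.
#' @param period_frames frames per full rotation (positive real, >= 8).
#' @param pixel_size_um pixel pitch, um.
#' @param dim image shape `c(rows, cols)`.
#' @param frame_interval_s acquisition interval, seconds.
#' @param drift_px_per_frame deterministic drift `c(dx, dy)` px/frame.
#' @param drift_walk_sd standard deviation of a random-walk drift step, px.
#' @param psf_sigma_px Gaussian PSF sigma, px. The objectives' NA is not
#'   modelled explicitly; this width is a free acquisition parameter.
#' @param noise_sigma additive Gaussian noise SD, fraction of dynamic range.
#' @param bg_level,bg_gradient background intensity and planar shading
#'   amplitude (fractions of dynamic range).
#' @param contrast peak specimen attenuation contrast.
#' @param attenuation_um optical attenuation length, um.
#' @param tail_fade fraction of the worm length over which tail contrast
#'   decays (0 disables fading).
#' @param tail_floor orientation-dependent tail contrast floor
#'   `c(worst, best)`: the floor varies smoothly between the two as the
#'   specimen rotates, so the tail is visible only at some orientations.
#' @param seed integer seed for drift and noise.
#' @return an object of class `render_spec`.
#' @export
render_spec <- function(n_frames, period_frames, pixel_size_um,
                        dim = c(96, 320), frame_interval_s = 0.4,
                        drift_px_per_frame = c(0, 0), drift_walk_sd = 0,
                        psf_sigma_px = 1.2, noise_sigma = 0.02,
                        bg_level = 0.85, bg_gradient = 0.05,
                        contrast = 0.55, attenuation_um = 25,
                        tail_fade = 0, tail_floor = c(0.02, 0.85),
                        seed = 1L) {
  if (period_frames < 8) stopf("period_frames must be >= 8")
  if (n_frames < period_frames) stopf("n_frames must be >= period_frames")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  structure(list(n_frames = as.integer(n_frames),
                 period_frames = period_frames,
                 pixel_size_um = pixel_size_um, dim = as.integer(dim),
                 frame_interval_s = frame_interval_s,
                 drift_px_per_frame = drift_px_per_frame,
                 drift_walk_sd = drift_walk_sd,
                 psf_sigma_px = psf_sigma_px, noise_sigma = noise_sigma,
                 bg_level = bg_level, bg_gradient = bg_gradient,
                 contrast = contrast, attenuation_um = attenuation_um,
                 tail_fade = tail_fade, tail_floor = tail_floor,
                 seed = as.integer(seed)), class = "render_spec")
}

#' Render the rotation image stack of a phantom
#'
#' Frame `i` (1-based) is the orthographic projection of the phantom rotated
#' by `theta_i = 2*pi*(i-1)/period_frames` about the image-horizontal axis
#' through its centroid, translated by the drift trace, attenuated through a
#' Beer-Lambert-style contrast model, blurred by the PSF, shaded and noised.
#' The tail fade multiplies the optical density of the tail region by an
#' orientation-dependent factor; the geometry itself is untouched, so the
#' ground truth is unaffected (which is what makes tail feature completion
#' testable downstream).
#'
#' @param phantom a [build_phantom()] result.
#' @param rspec a [render_spec()].
#' @return a list of class `phantom_render`: `stack` (an [image_stack()]),
#'   `angles_rad` (true frame angles), `drift_px` (n x 2 trace),
#'   `clean_frames` (noise-free renders), `true_masks` (exact silhouettes),
#'   `tail_visible` (per frame, worms with fading only), and `phantom`.
#' @export
render_stack <- function(phantom, rspec) {
  stopifnot(inherits(phantom, "phantom"), inherits(rspec, "render_spec"))
  if (!any(phantom$grid)) stopf("phantom grid is empty")
  if (phantom$voxel_um > rspec$pixel_size_um / 2 + 1e-9)
    stopf("phantom voxel pitch (%g um) must be at most half the render pixel size (%g um) so the projection grid is fully sampled",
          phantom$voxel_um, rspec$pixel_size_um)
  nr <- rspec$dim[1]; nc <- rspec$dim[2]; px <- rspec$pixel_size_um
  occ <- which(phantom$grid)
  ci <- arrayInd(occ, dim(phantom$grid))
  X <- phantom$x_um[ci[, 1]]; Y <- phantom$y_um[ci[, 2]]; Z <- phantom$z_um[ci[, 3]]
  dens <- phantom$density[occ]
  xb <- mean(X); yb <- mean(Y); zb <- mean(Z)
  X <- X - xb; Y <- Y - yb; Z <- Z - zb
  crow <- (nr + 1) / 2; ccol <- (nc + 1) / 2

  n <- rspec$n_frames
  drift <- matrix(0, n, 2) # columns dx, dy (px)
  theta <- 2 * pi * (0:(n - 1)) / rspec$period_frames
  spec <- phantom$spec
  s_frac <- (X + xb - min(phantom$x_um)) / spec$length_um
  vox <- phantom$voxel_um

  ## background shading field (fixed pattern)
  rn <- (seq_len(nr) - 1) / max(nr - 1, 1) - 0.5
  cn <- (seq_len(nc) - 1) / max(nc - 1, 1) - 0.5
  bg <- rspec$bg_level + rspec$bg_gradient * outer(0.6 * rn, cn, "+")

  fade_of <- function(th) {
    if (rspec$tail_fade <= 0 || spec$kind != "worm") return(rep(1, length(X)))
    floor_th <- rspec$tail_floor[1] +
      diff(rspec$tail_floor) * (1 + cos(th)) / 2
    ## smooth shoulder into a flat contrast floor: the whole tail region
    ## (not just the tip) drops to the orientation-dependent floor
    s0 <- 1 - rspec$tail_fade
    w <- 0.25 * rspec$tail_fade
    t <- clamp((s_frac - s0) / w, 0, 1)
    ss <- t * t * (3 - 2 * t)
    1 + (floor_th - 1) * ss
  }

  frames <- array(0, c(nr, nc, n))
  clean <- array(0, c(nr, nc, n))
  true_masks <- array(FALSE, c(nr, nc, n))
  tail_visible <- rep(NA, n)

  with_seed(rspec$seed, {
    if (rspec$drift_walk_sd > 0) {
      drift[, 1] <- cumsum(rnorm(n, 0, rspec$drift_walk_sd))
      drift[, 2] <- cumsum(rnorm(n, 0, rspec$drift_walk_sd))
    } else {
      drift[, 1] <- rspec$drift_px_per_frame[1] * (0:(n - 1))
      drift[, 2] <- rspec$drift_px_per_frame[2] * (0:(n - 1))
    }
    noise <- array(rnorm(nr * nc * n, 0, rspec$noise_sigma), c(nr, nc, n))

    ## the optical chain is simulated in physical order on a grid `ss`
    ## times finer than the sensor: thickness accumulation and Beer-Lambert
    ## attenuation (the object), Gaussian PSF (the optics), then box
    ## integration over each sensor pixel (the camera aperture)
    ss <- 2L
    bin_down <- function(fine) {
      b <- fine[seq(1, ss * nr, by = ss), seq(1, ss * nc, by = ss)]
      for (o1 in seq_len(ss) - 1L) for (o2 in seq_len(ss) - 1L) {
        if (o1 == 0 && o2 == 0) next
        b <- b + fine[seq(1 + o1, ss * nr, by = ss),
                      seq(1 + o2, ss * nc, by = ss)]
      }
      b / ss^2
    }
    rn_f <- ((seq_len(ss * nr) - 0.5) / ss + 0.5 - 1) / max(nr - 1, 1) - 0.5
    cn_f <- ((seq_len(ss * nc) - 0.5) / ss + 0.5 - 1) / max(nc - 1, 1) - 0.5
    bg_f <- rspec$bg_level + rspec$bg_gradient * outer(0.6 * rn_f, cn_f, "+")

    for (i in seq_len(n)) {
      v <- Y * cos(theta[i]) + Z * sin(theta[i])
      rows <- crow + v / px + drift[i, 2]
      cols <- ccol + X / px + drift[i, 1]
      if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc)
        stopf("render error: image %dx%d too small for the rotated, drifted specimen",
              nr, nc)
      fd <- fade_of(theta[i])
      rows_f <- (rows - 0.5) * ss + 0.5
      cols_f <- (cols - 0.5) * ss + 0.5
      ## each voxel carries vox^3 um^3 of material spread over one fine
      ## pixel of area (px/ss)^2, so thickness is a true path length in um
      w_thick <- vox^3 * ss^2 / px^2
      ## bilinear deposit on the fine grid: a voxel centre falling exactly
      ## between two fine pixels is split between them, which keeps the
      ## projection unbiased (nearest-pixel rounding would shift the whole
      ## image by a quarter pixel whenever the lattice aligns with the
      ## fine-grid boundaries); the tent kernel is half a sensor pixel wide
      thick <- .splat_project(rows_f, cols_f, dens * fd * w_thick,
                              ss * nr, ss * nc)
      img_f <- bg_f - rspec$contrast * (1 - exp(-thick / rspec$attenuation_um))
      img_f <- gauss_blur_fft(img_f, rspec$psf_sigma_px * ss)
      img <- bin_down(img_f)
      clean[, , i] <- img
      frames[, , i] <- clamp(img + noise[, , i], 0, 1)
      geom <- .splat_project(floor(rows + 0.5 + 1e-9),
                             floor(cols + 0.5 + 1e-9),
                             rep(vox, length(rows)), nr, nc)
      true_masks[, , i] <- geom > 0.5 * vox
      if (rspec$tail_fade > 0 && spec$kind == "worm")
        tail_visible[i] <- rspec$tail_floor[1] +
          diff(rspec$tail_floor) * (1 + cos(theta[i])) / 2 > 0.3
    }
  })

  stack <- image_stack(frames, pixel_size_um = px,
                       frame_interval_s = rspec$frame_interval_s,
                       provenance = sprintf("phantom:%s seed %d", spec$kind,
                                            rspec$seed))
  structure(list(stack = stack, angles_rad = theta, drift_px = drift,
                 clean_frames = clean, true_masks = true_masks,
                 tail_visible = tail_visible, phantom = phantom,
                 rspec = rspec),
            class = "phantom_render")
}

#' Read or write phantom/render specifications as YAML
#'
#' @param path YAML file path.
#' @param spec a `phantom_spec` or `render_spec`.
#' @return `read_phantom_yaml()` returns a list with elements `phantom`
#'   (class `phantom_spec`) and, when present, `render` (class
#'   `render_spec`).
#' @export
write_phantom_yaml <- function(spec, path, render = NULL) {
  out <- list(phantom = unclass(spec))
  if (!is.null(render)) out$render <- unclass(render)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$phantom)) stopf("YAML %s lacks a 'phantom' block", path)
  ph <- do.call(phantom_spec, y$phantom)
  out <- list(phantom = ph)
  if (!is.null(y$render)) out$render <- do.call(render_spec, y$render)
  out
}

#' Write the ground truth of a phantom (metrics + angles as JSON, mesh as PLY)
#'
#' @param render a `phantom_render`.
#' @param dir output directory.
#' @export
write_ground_truth <- function(render, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- render$phantom$gt
  jsonlite::write_json(
    list(metrics = gt[c("surface_area_um2", "volume_um3", "length_um",
                        "max_width_um", "ratio")],
         angles_rad = render$angles_rad,
         drift_px = render$drift_px),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  write_ply(gt$mesh, file.path(dir, "ground_truth.ply"))
  invisible(dir)
}
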