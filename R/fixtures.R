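## Reference phantom acquisition conditions. These mirror the specimens the
## rotation rig targets: adult worms about 1 mm long with a maximum diameter
## about 50 um imaged at low magnification, and gastrulation-stage embryos
## about 50 x 30 um imaged at higher magnification. The cohort generators
## draw specimen-to-specimen variation from fixed documented ranges.

#' Standard phantom acquisition conditions
#'
#' The reference adult is a gently bent, tapered 1000 x 50 um worm imaged at
#' 4 um/px over 96 frames with a 64-frame rotation period; the reference
#' embryo is a bumped 50 x 30 um ovoid imaged at 0.5 um/px over 72 frames
#' with a 48-frame period. Both are rendered with 2% additive noise, a 1.2
#' px PSF and a 5% background shading field, zero drift.
#'
#' @param kind `"adult"` or `"embryo"`.
#' @param seed integer seed (drives landmarks, bump phases, noise).
#' @param noise_sigma additive noise SD (fraction of dynamic range).
#' @param tail_fade worm tail-fade fraction (0 = no fading).
#' @return list with `spec` ([phantom_spec()]) and `rspec`
#'   ([render_spec()]).
#' @export
standard_phantom <- function(kind = c("adult", "embryo"), seed = 1L,
                             noise_sigma = 0.02, tail_fade = 0) {
  kind <- match.arg(kind)
  if (kind == "adult") {
    spec <- phantom_spec("worm", length_um = 1000, max_radius_um = 25,
                         taper = 0.15, cap_frac = 0.12,
                         bend_amplitude_um = 40, bend_wavelength_um = 900,
                         bend_phase = 0.6, rng_seed = seed)
    rspec <- render_spec(n_frames = 96, period_frames = 64,
                         pixel_size_um = 4, dim = c(64, 288),
                         noise_sigma = noise_sigma, tail_fade = tail_fade,
                         seed = seed)
  } else {
    spec <- phantom_spec("embryo", semi_axes_um = c(25, 15, 15),
                         bump_amplitude = 0.05, bump_freq = 3,
                         rng_seed = seed)
    rspec <- render_spec(n_frames = 72, period_frames = 48,
                         pixel_size_um = 0.5, dim = c(96, 160),
                         noise_sigma = noise_sigma, seed = seed)
  }
  list(spec = spec, rspec = rspec)
}

#' Cohort phantom with randomized morphology
#'
#' Draws one specimen of a synthetic cohort. Adults vary in length
#' (850-1100 um), maximum radius (22-28 um), bend amplitude (10-50 um),
#' bend wavelength (0.7-1.0 body lengths) and taper (0.05-0.3); embryos
#' vary in semi-axes (a 22-28 um, b and c 13-17 um) and surface bumps
#' (relative amplitude 0.02-0.07, angular frequency 2-4). Acquisition
#' settings match [standard_phantom()].
#'
#' @inheritParams standard_phantom
#' @return list with `spec` and `rspec`.
#' @export
cohort_phantom <- function(kind = c("adult", "embryo"), seed = 1L,
                           noise_sigma = 0.02) {
  kind <- match.arg(kind)
  with_seed(seed * 101L + 17L, {
    if (kind == "adult") {
      L <- runif(1, 850, 1100)
      spec <- phantom_spec("worm", length_um = L,
                           max_radius_um = runif(1, 22, 28),
                           taper = runif(1, 0.05, 0.3), cap_frac = 0.12,
                           bend_amplitude_um = runif(1, 10, 50),
                           bend_wavelength_um = runif(1, 0.7, 1.0) * L,
                           bend_phase = runif(1, 0, 2 * pi), rng_seed = seed)
      rspec <- render_spec(n_frames = 96, period_frames = 64,
                           pixel_size_um = 4, dim = c(64, 320),
                           noise_sigma = noise_sigma, seed = seed)
    } else {
      spec <- phantom_spec("embryo",
                           semi_axes_um = c(runif(1, 22, 28),
                                            runif(1, 13, 17),
                                            runif(1, 13, 17)),
                           bump_amplitude = runif(1, 0.02, 0.07),
                           bump_freq = sample(2:4, 1), rng_seed = seed)
      rspec <- render_spec(n_frames = 72, period_frames = 48,
                           pixel_size_um = 0.5, dim = c(96, 160),
                           noise_sigma = noise_sigma, seed = seed)
    }
    list(spec = spec, rspec = rspec)
  })
}

#' Reconstruct one phantom end to end
#'
#' Convenience wrapper used by examples and validation studies: builds and
#' renders the phantom, then runs the full pipeline on the rendered stack.
#'
#' @param conditions a list with `spec` and `rspec` (see
#'   [standard_phantom()]).
#' @param voxel_um phantom voxelization pitch; default half a pixel.
#' @param config optional pipeline configuration overrides (nested list).
#' @return the [run_pipeline()] report, with the `phantom_render` attached
#'   as `$render`.
#' @export
reconstruct_phantom <- function(conditions, voxel_um = NULL, config = list()) {
  vox <- voxel_um %||% (conditions$rspec$pixel_size_um / 2)
  ph <- build_phantom(conditions$spec, vox)
  rnd <- render_stack(ph, conditions$rspec)
  cfg <- utils::modifyList(
    list(input = list(stack = "memory"),
         calibration = list(pixel_size_um = conditions$rspec$pixel_size_um),
         phenotype = list(stage = if (conditions$spec$kind == "embryo")
           "embryo" else "adult")),
    config)
  out <- run_pipeline(cfg, stack = rnd$stack)
  out$render <- rnd
  out
}

#' Reprojection-IoU validation run for one phantom
#'
#' The reconstruction-accuracy experiment: build and render the phantom,
#' run enhancement (with 2x super-resolution by default, which halves the
#' silhouette quantization scale), segmentation, period estimation,
#' alignment, angle assignment and carving, then score reprojection IoU at
#' the standard viewpoints (0-180 degrees in steps of 30). The surface mesh
#' and morphometry stages are not needed for IoU and are skipped.
#'
#' @param conditions a list with `spec` and `rspec` (see
#'   [standard_phantom()], [cohort_phantom()]).
#' @param upsample_factor enhancement upsampling for the validation run.
#' @param viewpoints_deg viewpoint angles, degrees.
#' @return an `iou_report`.
#' @export
phantom_iou <- function(conditions, upsample_factor = 2,
                        viewpoints_deg = seq(0, 180, by = 30)) {
  ph <- build_phantom(conditions$spec, conditions$rspec$pixel_size_um / 2)
  rnd <- render_stack(ph, conditions$rspec)
  enh <- enhance(rnd$stack, upsample_factor = upsample_factor)
  sils <- segment(enh, psf_sigma_px = 1.2 * upsample_factor,
                  aperture_px = upsample_factor,
                  deconv_sigma_px = 1.2 * upsample_factor)
  ## the period needs no spatial resolution: estimate it on the raw stack
  est <- estimate_period(rnd$stack)
  sils <- align_frames(sils, est$period_frames)
  sils <- assign_angles(est, sils)
  vol <- carve_slicewise(sils)
  validate_reconstruction(vol, sils, viewpoints_deg)
}
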