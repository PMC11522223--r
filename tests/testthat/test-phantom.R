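# phantom module: ground-truth metrics, rendering physics, determinism

test_that("closed-form ground truth matches analytic solids", {
  sph <- build_phantom(phantom_spec("sphere", max_radius_um = 25), 1)
  expect_equal(sph$gt$volume_um3, 4 / 3 * pi * 25^3, tolerance = 1e-9)
  expect_equal(sph$gt$surface_area_um2, 4 * pi * 25^2, tolerance = 1e-9)

  ell <- build_phantom(phantom_spec("ellipsoid",
                                    semi_axes_um = c(25, 15, 15)), 1)
  expect_equal(ell$gt$volume_um3, 4 / 3 * pi * 25 * 15 * 15, tolerance = 1e-9)
  expect_equal(ell$gt$length_um, 50)
  expect_equal(ell$gt$max_width_um, 30)

  cyl <- build_phantom(phantom_spec("cylinder", length_um = 200,
                                    max_radius_um = 20), 2)
  expect_equal(cyl$gt$volume_um3, pi * 400 * 200, tolerance = 1e-9)
  expect_equal(cyl$gt$ratio, 200 / 40, tolerance = 1e-9)
})

test_that("quadrature ground truth is self-consistent with fine voxel counts", {
  spec <- phantom_spec("worm", length_um = 240, max_radius_um = 16,
                       bend_amplitude_um = 12, bend_wavelength_um = 220,
                       rng_seed = 2)
  v1 <- sum(build_phantom(spec, 1)$grid) * 1^3
  v05 <- sum(build_phantom(spec, 0.5)$grid) * 0.5^3
  gt <- phantom_ground_truth(spec)
  expect_lt(abs(v05 - gt$volume_um3) / gt$volume_um3, 0.01)
  expect_lt(abs(v05 / v1 - 1), 0.01) # halving the voxel changes volume < 1%

  em <- phantom_spec("embryo", rng_seed = 3)
  gt_e <- phantom_ground_truth(em)
  v_e <- sum(build_phantom(em, 0.4)$grid) * 0.4^3
  expect_lt(abs(v_e - gt_e$volume_um3) / gt_e$volume_um3, 0.01)
  # the parametric ground-truth mesh agrees with the quadrature area
  expect_lt(abs(mesh_area(gt_e$mesh) - gt_e$surface_area_um2) /
              gt_e$surface_area_um2, 0.01)
})

test_that("degenerate specs and inadequate sampling are rejected", {
  expect_error(phantom_spec("worm", length_um = 0), "length_um")
  expect_error(phantom_spec("worm", max_radius_um = -3), "max_radius_um")
  expect_error(phantom_spec("worm", length_um = 40, max_radius_um = 25),
               "2\\*max_radius_um")
  expect_error(phantom_spec("embryo", semi_axes_um = c(25, 0, 15)),
               "semi-axes")
  expect_error(build_phantom(phantom_spec("sphere", max_radius_um = 20), 10),
               "too coarse")
})

test_that("phantom occupancy is a single connected component", {
  ph <- small_worm_fixture()$ph
  lab <- rotomorph:::`.largest_component`
  kept <- array(lab(ph$grid, dim(ph$grid)), dim(ph$grid))
  expect_identical(sum(kept), sum(ph$grid))
})

test_that("rendering is periodic, symmetric for spheres, and seeded", {
  sph <- build_phantom(phantom_spec("sphere", max_radius_um = 20), 1)
  rs <- render_spec(n_frames = 20, period_frames = 10, pixel_size_um = 2,
                    dim = c(48, 48), noise_sigma = 0, seed = 7)
  rnd <- render_stack(sph, rs)
  # zero noise/drift, integer period: frame 1 and frame 1+P identical
  expect_equal(rnd$stack$frames[, , 1], rnd$stack$frames[, , 11])
  # rotational symmetry: every silhouette is the same disk up to voxel
  # quantization at the limb
  for (i in 2:20)
    expect_gte(iou(rnd$true_masks[, , i], rnd$true_masks[, , 1]), 0.97)

  cond <- small_worm_conditions(seed = 4)
  ph <- build_phantom(cond$spec, 1)
  a <- render_stack(ph, cond$rspec)
  b <- render_stack(ph, cond$rspec)
  expect_identical(a$stack$frames, b$stack$frames) # bit-identical given seed
})

test_that("silhouette area of a bent worm varies with the rotation period", {
  fx <- small_worm_fixture()
  areas <- apply(fx$rnd$true_masks, 3, sum)
  ac <- stats::acf(areas - mean(areas), lag.max = 30, plot = FALSE)$acf[-1]
  # periodic with period P (area trace repeats every P frames; the first
  # harmonic at P/2 may also be strong for a near-symmetric bend)
  P <- fx$cond$rspec$period_frames
  peaks <- which(ac > 0.7 * max(ac))
  expect_true(any(abs(peaks - P) <= 1) || any(abs(peaks - P / 2) <= 1))
})

test_that("a specimen larger than the frame is a render error", {
  ph <- build_phantom(phantom_spec("cylinder", length_um = 400,
                                   max_radius_um = 20), 1)
  rs <- render_spec(n_frames = 12, period_frames = 12, pixel_size_um = 2,
                    dim = c(32, 64), seed = 1)
  expect_error(render_stack(ph, rs), "too small")
})

test_that("phantom YAML and ground truth round-trip through files", {
  td <- withr::local_tempdir()
  cond <- small_worm_conditions(seed = 5)
  yml <- file.path(td, "phantom.yaml")
  write_phantom_yaml(cond$spec, yml, render = cond$rspec)
  back <- read_phantom_yaml(yml)
  expect_equal(back$phantom$length_um, cond$spec$length_um)
  expect_equal(back$render$period_frames, cond$rspec$period_frames)

  ph <- build_phantom(cond$spec, 1)
  rnd <- render_stack(ph, cond$rspec)
  write_ground_truth(rnd, td)
  gt <- jsonlite::read_json(file.path(td, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$metrics$volume_um3, ph$gt$volume_um3, tolerance = 1e-8)
  expect_length(gt$angles_rad, cond$rspec$n_frames)
  expect_true(read_ply(file.path(td, "ground_truth.ply"))$watertight)
})
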