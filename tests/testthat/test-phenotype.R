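# phenotype module: the five morphometric metrics on exact geometry
# (phantom occupancy grids) and on reconstructed volumes

test_that("voxel volume arithmetic is exact", {
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE
  vol <- structure(list(grid = g, voxel_um = 2, cols = 1:3, y_um = (-1:1) * 2,
                        z_um = (-1:1) * 2, axis_row = 2, img_dim = c(3, 3),
                        pixel_size_um = 2), class = "voxel_volume")
  expect_equal(measure_volume(vol), 8)
})

test_that("a cylinder yields its closed-form metrics", {
  ph <- build_phantom(phantom_spec("cylinder", length_um = 300,
                                   max_radius_um = 25), 1.5)
  vol <- vol_from_phantom(ph)
  mesh <- extract_mesh(vol)
  cl <- extract_centerline(vol)
  expect_lt(abs(cl$length_um - 300) / 300, 0.02)
  wid <- measure_max_width(vol, mesh, cl)
  expect_lt(abs(wid$max_width_um - 50), 2 * vol$voxel_um)
  rec <- phenotype(vol, mesh, sample_id = "cyl", stage = "adult",
                   centerline = cl)
  expect_equal(rec$ratio, rec$length_um / rec$max_width_um, tolerance = 1e-9)
  expect_lt(abs(rec$ratio - 6) / 6, 0.05)
  # mid cross-section is a circle of the cylinder radius
  cs <- cross_section(vol, mesh, cl, 0.5)
  expect_equal(cs[1, ], cs[nrow(cs), ]) # closed outline
  rad <- sqrt(rowSums(scale(cs, scale = FALSE)^2))
  expect_lt(max(abs(rad - 25)), 1.6 * vol$voxel_um)
})

test_that("a bent worm's centerline follows the arc, not the chord", {
  spec <- phantom_spec("worm", length_um = 260, max_radius_um = 16,
                       bend_amplitude_um = 30, bend_wavelength_um = 200,
                       bend_phase = 0.3, rng_seed = 9)
  ph <- build_phantom(spec, 1)
  vol <- vol_from_phantom(ph)
  cl <- extract_centerline(vol)
  expect_lt(abs(cl$length_um - ph$gt$length_um) / ph$gt$length_um, 0.03)
  chord <- sqrt(sum((cl$points[nrow(cl$points), ] - cl$points[1, ])^2))
  expect_gt(cl$length_um, chord)
})

test_that("a sphere degenerates to length ~ diameter", {
  vol <- sphere_volume(r = 16, vox = 1)
  cl <- extract_centerline(vol)
  expect_lt(abs(cl$length_um - 32) / 32, 0.05)
})

test_that("the maximum width sits at the radius-profile maximum", {
  spec <- phantom_spec("worm", length_um = 260, max_radius_um = 18,
                       taper = 0.35, cap_frac = 0.15, rng_seed = 2)
  ph <- build_phantom(spec, 1)
  vol <- vol_from_phantom(ph)
  mesh <- extract_mesh(vol)
  cl <- extract_centerline(vol)
  wid <- measure_max_width(vol, mesh, cl)
  expect_lt(abs(wid$arc_position - ph$gt$max_width_pos), 0.05)
  expect_lt(abs(wid$max_width_um - ph$gt$max_width_um) /
              ph$gt$max_width_um, 0.05)
})

test_that("metrics in um are invariant to the sampling resolution", {
  spec <- phantom_spec("worm", length_um = 220, max_radius_um = 16,
                       bend_amplitude_um = 10, bend_wavelength_um = 200,
                       rng_seed = 5)
  recs <- lapply(c(1, 0.6), function(vox) {
    ph <- build_phantom(spec, vox)
    vol <- vol_from_phantom(ph)
    phenotype(vol, extract_mesh(vol), stage = "adult")
  })
  for (m in c("volume_um3", "surface_area_um2", "length_um", "max_width_um"))
    expect_lt(abs(recs[[1]][[m]] - recs[[2]][[m]]) / recs[[2]][[m]], 0.04)
})

test_that("the embryo record matches its reported proportions", {
  ph <- build_phantom(phantom_spec("ellipsoid", semi_axes_um = c(25, 15, 15)),
                      0.75)
  vol <- vol_from_phantom(ph)
  rec <- phenotype(vol, extract_mesh(vol), stage = "embryo")
  expect_lt(abs(rec$ratio - 50 / 30) / (50 / 30), 0.05)
  expect_lt(abs(rec$volume_um3 - ph$gt$volume_um3) / ph$gt$volume_um3, 0.03)
})

test_that("records append to CSV one row per specimen", {
  vol <- sphere_volume(r = 10, vox = 1)
  rec <- phenotype(vol, extract_mesh(vol), sample_id = "s1", stage = "embryo")
  td <- withr::local_tempdir()
  p <- file.path(td, "metrics.csv")
  append_records_csv(rec, p)
  append_records_csv(rec, p)
  expect_equal(nrow(read.csv(p)), 2)
})
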