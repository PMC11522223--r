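# SurfaceMesh: iso-surface extraction, smoothing, metrics, I/O

test_that("a sphere volume meshes to the analytic area and volume", {
  vol <- sphere_volume(r = 20, vox = 1)
  mesh <- extract_mesh(vol)
  expect_true(mesh$watertight)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 400) / (4 * pi * 400), 0.03)
  # divergence-theorem volume agrees with the voxel count within 2%
  expect_lt(abs(mesh_volume(mesh) - measure_volume(vol)) /
              measure_volume(vol), 0.02)
  expect_gt(mesh_volume(mesh), 0) # outward orientation
})

test_that("Taubin smoothing preserves volume", {
  vol <- sphere_volume(r = 15, vox = 1)
  m0 <- extract_mesh(vol, smooth_iters = 0)
  m10 <- extract_mesh(vol, smooth_iters = 10)
  expect_lt(abs(mesh_volume(m10) - mesh_volume(m0)) / mesh_volume(m0), 0.01)
})

test_that("mesh area is invariant under rigid transforms", {
  mesh <- extract_mesh(sphere_volume(r = 10, vox = 1))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- mesh
  moved$vertices <- sweep(mesh$vertices %*% t(R), 2, c(5, -3, 11), "+")
  expect_equal(mesh_area(moved), mesh_area(mesh), tolerance = 1e-9)
})

test_that("unit cube mesh has area 6 and volume 1", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind( # 12 triangles, outward orientation
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- surface_mesh(v, f)
  expect_equal(mesh_area(cube), 6)
  expect_equal(abs(mesh_volume(cube)), 1)
  expect_true(is_watertight(cube))
})

test_that("meshes round-trip through PLY and STL writers", {
  mesh <- extract_mesh(sphere_volume(r = 8, vox = 1))
  td <- withr::local_tempdir()
  ply <- file.path(td, "m.ply")
  write_ply(mesh, ply)
  back <- read_ply(ply)
  expect_equal(back$vertices, unname(mesh$vertices), tolerance = 1e-6)
  expect_identical(back$faces, mesh$faces)
  expect_true(back$watertight)
  stl <- file.path(td, "m.stl")
  write_stl(mesh, stl)
  expect_gt(length(readLines(stl)), 7 * nrow(mesh$faces))
})
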