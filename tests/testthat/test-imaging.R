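# imaging module: enhancement and silhouette segmentation

test_that("enhancement keeps constants constant and tracks calibration", {
  st <- image_stack(array(0.5, c(32, 40, 2)), pixel_size_um = 2)
  enh <- enhance(st, denoise = FALSE, deconv_sigma_px = 0)
  expect_equal(enh$frames, st$frames, tolerance = 1e-6)

  st2 <- image_stack(array(runif(32 * 40), c(32, 40, 1)), pixel_size_um = 2)
  up <- enhance(st2, upsample_factor = 2)
  expect_equal(dim(up$frames)[1:2], c(64, 80))
  expect_equal(up$pixel_size_um, 1)
})

test_that("enhancement reduces the error against the clean render", {
  cond <- small_worm_conditions(seed = 6, noise = 0.05)
  cond$rspec$bg_gradient <- 0 # flat field isolates the denoising effect
  ph <- build_phantom(cond$spec, 1)
  rnd <- render_stack(ph, cond$rspec)
  ctr <- function(a) a - mean(a)
  noisy <- rnd$stack$frames[, , 1]
  clean <- rnd$clean_frames[, , 1]
  enh <- enhance(rnd$stack, deconv_sigma_px = 0)$frames[, , 1]
  mae_before <- mean(abs(ctr(noisy) - ctr(clean)))
  mae_after <- mean(abs(ctr(enh) - ctr(clean)))
  expect_lt(mae_after, mae_before)
})

test_that("a noiseless sphere render segments to its true disk", {
  sph <- build_phantom(phantom_spec("sphere", max_radius_um = 20), 0.25)
  rs <- render_spec(n_frames = 12, period_frames = 12, pixel_size_um = 0.5,
                    dim = c(128, 128), noise_sigma = 0, seed = 2)
  rnd <- render_stack(sph, rs)
  sils <- segment(enhance(rnd$stack))
  expect_false(any(sils$failed))
  # reference: the projected disk rasterized by the pixel-centre convention
  disk <- outer((1:128) - 64.5, (1:128) - 64.5,
                function(a, b) a^2 + b^2 <= 40^2)
  for (i in c(1, 6)) {
    expect_gte(iou(sils$masks[, , i], disk), 0.98)
    expect_equal(sum(rotomorph:::`.largest_component`(
      array(sils$masks[, , i], c(128, 128, 1)), c(128L, 128L, 1L))),
      sum(sils$masks[, , i])) # single connected component
  }
})

test_that("background-only frames are flagged, never zero-filled", {
  frames <- array(0.8, c(48, 64, 3))
  frames[20:28, 20:44, 1] <- 0.3 # only frame 1 has a specimen
  set.seed(1)
  frames <- frames + array(rnorm(length(frames), 0, 0.01), dim(frames))
  sils <- segment(image_stack(frames, 2), close_radius = 1)
  expect_false(sils$failed[1])
  expect_true(all(sils$failed[2:3]))
  expect_equal(sum(sils$masks[, , 2]), 0)
})

test_that("segmentation is idempotent on its own output", {
  fx <- small_worm_fixture()
  i <- 1
  mask_img <- array(fx$sils$masks[, , i] * 1, c(dim(fx$sils$masks)[1:2], 1))
  again <- segment(image_stack(mask_img, 2), polarity = "bright",
                   close_radius = 1)
  expect_gte(iou(again$masks[, , 1], fx$sils$masks[, , i]), 0.97)
})

test_that("confident extent excludes faded tail columns and is monotone", {
  cond <- small_worm_conditions(seed = 7, tail_fade = 0.3)
  ph <- build_phantom(cond$spec, 1)
  rnd <- render_stack(ph, cond$rspec)
  sils <- segment(enhance(rnd$stack))
  full <- segment(enhance(render_stack(ph,
    small_worm_conditions(seed = 7, tail_fade = 0)$rspec)$stack))

  faded <- which(!rnd$tail_visible)
  visible <- which(rnd$tail_visible)
  expect_gt(length(faded), 3)
  # the generator fades the high-column (tail) end: faded frames end well
  # short of the frames that see the tail
  expect_lt(median(sils$extent[faded, 2]), median(sils$extent[visible, 2]) - 4)
  # removing the fade never shortens the confident extent (per frame)
  expect_true(all(full$extent[, 2] >= sils$extent[, 2] - 1))
  # bright body columns stay inside the extent even in faded frames
  body_hi <- round(median(full$extent[, 2]) * 0.7)
  expect_true(all(sils$extent[faded, 2] >= body_hi * 0.8))
})

test_that("masks round-trip through the TIFF writer", {
  fx <- small_worm_fixture()
  td <- withr::local_tempdir()
  p <- file.path(td, "masks.tif")
  write_masks(fx$sils, p)
  back <- read_stack(p, pixel_size_um = fx$sils$pixel_size_um)
  expect_equal(dim(back$frames), dim(fx$sils$masks))
  expect_equal(back$frames[, , 3] > 0.5, fx$sils$masks[, , 3])
})
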