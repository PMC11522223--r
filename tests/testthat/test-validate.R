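# validate module: reprojection and IoU scoring

test_that("IoU identities hold", {
  a <- matrix(FALSE, 20, 20); a[3:12, 3:12] <- TRUE
  expect_equal(iou(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[15:18, 15:18] <- TRUE
  expect_equal(iou(a, b), 0)
  shifted <- matrix(FALSE, 20, 20); shifted[3:12, 8:17] <- TRUE
  expect_equal(iou(a, shifted), 50 / 150) # 10x10 square shifted by 5 px
  expect_error(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "undefined")
  expect_error(iou(a, matrix(TRUE, 5, 5)), "same shape")
})

test_that("IoU is symmetric and translation-invariant", {
  set.seed(42)
  a <- matrix(FALSE, 20, 20); b <- matrix(FALSE, 20, 20)
  a[6:12, 5:11] <- matrix(runif(49) > 0.5, 7)
  b[7:13, 6:12] <- matrix(runif(49) > 0.5, 7)
  expect_equal(iou(a, b), iou(b, a))
  expect_equal(iou(rotomorph:::shift_matrix(a, 2, 3),
                   rotomorph:::shift_matrix(b, 2, 3)), iou(a, b))
})

test_that("reprojection respects symmetry and angle periodicity", {
  vol <- sphere_volume(r = 12, vox = 1)
  m0 <- reproject(vol, 0)
  # the same disk at every angle, up to voxel quantization at the limb
  for (ang in c(37, 90, 233)) expect_gte(iou(reproject(vol, ang), m0), 0.95)
  fx <- small_worm_fixture()
  expect_identical(reproject(fx$vol, 73), reproject(fx$vol, 73 + 360))
})

test_that("validation matches viewpoints to nearest frames and warns on gaps", {
  fx <- small_worm_fixture()
  rep <- validate_reconstruction(fx$vol, fx$sils)
  expect_equal(rep$n, 7)
  expect_equal(rep$mean, mean(rep$per_view$iou))
  step <- 360 / fx$sils$period_frames
  expect_true(all(abs(rep$per_view$viewpoint_deg -
                        rep$per_view$frame_angle_deg) <= step / 2 + 1e-9))
  # remove the frames near 90 degrees: that viewpoint is skipped
  sils2 <- fx$sils
  near90 <- which(abs(sils2$angles_rad * 180 / pi - 90) < step)
  sils2$selected[near90] <- FALSE
  sils2$angles_rad[near90] <- NA
  expect_warning(r2 <- validate_reconstruction(fx$vol, sils2), "skipped")
  expect_lt(r2$n, 7)
})

test_that("inflating the model strictly lowers the IoU", {
  fx <- small_worm_fixture()
  base <- validate_reconstruction(fx$vol, fx$sils)
  fat <- fx$vol
  g <- fat$grid
  for (k in 1:3) { # dilate 3 voxels in the cross-section plane
    d <- g
    d[, -1, ] <- d[, -1, ] | g[, -dim(g)[2], ]
    d[, -dim(g)[2], ] <- d[, -dim(g)[2], ] | g[, -1, ]
    d[, , -1] <- d[, , -1] | g[, , -dim(g)[3]]
    d[, , -dim(g)[3]] <- d[, , -dim(g)[3]] | g[, , -1]
    g <- d
  }
  fat$grid <- g
  expect_lt(validate_reconstruction(fat, fx$sils)$mean, base$mean)
})

test_that("IoU reports serialize to JSON and CSV", {
  fx <- small_worm_fixture()
  rep <- validate_reconstruction(fx$vol, fx$sils)
  td <- withr::local_tempdir()
  write_iou_report(rep, file.path(td, "iou.json"), file.path(td, "iou.csv"))
  j <- jsonlite::read_json(file.path(td, "iou.json"), simplifyVector = TRUE)
  expect_equal(j$mean, rep$mean, tolerance = 1e-12)
  expect_equal(nrow(read.csv(file.path(td, "iou.csv"))), rep$n)
})
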