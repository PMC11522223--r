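# hull module: strip-intersection carving, the brute-force oracle, and the
# analytic visual-hull limits

test_that("N identical rectangle silhouettes carve the regular 2N-gon", {
  r <- 16 # half-height, px = um
  for (N in c(4, 8)) {
    sils <- ideal_sils(N, c(rep(NA, 8), rep(r, 20), rep(NA, 36)),
                       ncol = 64, nrow = 64)
    vol <- carve_slicewise(sils, voxel_um = 0.25, n_min = N, min_contrib = 1,
                           miss_frac = 0)
    mid <- vol$grid[15, , ]
    area <- sum(mid) * 0.25^2
    expected <- 2 * N * r^2 * tan(pi / (2 * N))
    expect_lt(abs(area - expected) / expected, 0.02)
  }
})

test_that("with many angles the hull volume approaches the true sphere", {
  r <- 20
  half <- function(th) {
    x <- seq_len(64) - 32.5
    h <- sqrt(pmax(r^2 - x^2, 0))
    h[h <= 0] <- NA
    h
  }
  sils <- ideal_sils(90, half, ncol = 64, nrow = 64)
  vol <- carve_slicewise(sils, voxel_um = 0.5, n_min = 90, min_contrib = 1,
                         miss_frac = 0)
  v_true <- 4 / 3 * pi * r^3
  v_est <- measure_volume(vol)
  expect_gt(v_est, 0.97 * v_true)
  expect_lt(v_est, 1.03 * v_true) # hull excess 2N*tan(pi/2N)/pi -> 1
})

test_that("slicewise and brute-force carving agree voxel for voxel", {
  fx <- small_worm_fixture()
  a <- carve_slicewise(fx$sils)
  b <- carve_bruteforce(fx$sils, min_contrib = 8)
  expect_identical(a$grid, b$grid)
  # and with gating disabled
  a2 <- carve_slicewise(fx$sils, gate_extent = FALSE)
  b2 <- carve_bruteforce(fx$sils, gate_extent = FALSE, min_contrib = 8)
  expect_identical(a2$grid, b2$grid)
})

test_that("a single frame extrudes its silhouette; zero frames error", {
  sils <- ideal_sils(1, c(rep(NA, 10), rep(12.2, 30), rep(NA, 24)))
  vol <- carve_bruteforce(sils, min_contrib = 1)
  pr <- reproject(vol, 0)
  expect_equal(pr, sils$masks[, , 1])
  sils$selected[] <- FALSE
  expect_error(carve_bruteforce(sils), "no angle-stamped frames")
})

test_that("the carved hull is a superset of the true occupancy", {
  fx <- small_worm_fixture()
  vol <- fx$vol
  # map true voxels into the carved grid and check coverage (allowing a
  # 1-voxel boundary tolerance via dilation of the carved volume)
  ph <- fx$ph
  g <- vol$grid
  dil <- g
  dil[-1, , ] <- dil[-1, , ] | g[-dim(g)[1], , ]
  dil[-dim(g)[1], , ] <- dil[-dim(g)[1], , ] | g[-1, , ]
  dil[, -1, ] <- dil[, -1, ] | g[, -dim(g)[2], ]
  dil[, -dim(g)[2], ] <- dil[, -dim(g)[2], ] | g[, -1, ]
  dil[, , -1] <- dil[, , -1] | g[, , -dim(g)[3]]
  dil[, , -dim(g)[3]] <- dil[, , -dim(g)[3]] | g[, , -1]

  occ <- which(ph$grid)
  ci <- arrayInd(occ, dim(ph$grid))
  # phantom voxel centre -> image coordinates used in carving
  xb <- mean(ph$x_um[ci[, 1]]); yb <- mean(ph$y_um[ci[, 2]])
  zb <- mean(ph$z_um[ci[, 3]])
  px <- vol$pixel_size_um
  ccol <- (vol$img_dim[2] + 1) / 2
  col_i <- round(ccol + (ph$x_um[ci[, 1]] - xb) / px)
  gx <- match(col_i, vol$cols)
  y0 <- (length(vol$y_um) + 1) / 2
  gy <- round((ph$y_um[ci[, 2]] - yb) / vol$voxel_um + y0)
  gz <- round((ph$z_um[ci[, 3]] - zb) / vol$voxel_um + y0)
  ok <- !is.na(gx) & gy >= 1 & gy <= dim(g)[2] & gz >= 1 & gz <= dim(g)[3]
  covered <- dil[cbind(gx[ok], gy[ok], gz[ok])]
  expect_gt(mean(covered), 0.99)
})

test_that("hull volume decreases monotonically as frames are added", {
  r <- 16
  strip <- c(rep(NA, 8), rep(r, 20), rep(NA, 36))
  vols <- vapply(c(3, 6, 12, 24), function(N) {
    sils <- ideal_sils(N, strip)
    measure_volume(carve_slicewise(sils, voxel_um = 0.5, n_min = N,
                                   min_contrib = 1, miss_frac = 0))
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("an empty carve is a reconstruction failure with diagnostics", {
  sils <- ideal_sils(8, c(rep(NA, 10), rep(10, 20), rep(NA, 34)))
  # two frames with disjoint silhouettes empty every slice
  sils$sub_lo[, 1] <- ifelse(is.na(sils$sub_lo[, 1]), NA, 5)
  sils$sub_hi[, 1] <- ifelse(is.na(sils$sub_hi[, 1]), NA, 10)
  sils$sub_lo[, 5] <- ifelse(is.na(sils$sub_lo[, 5]), NA, 50)
  sils$sub_hi[, 5] <- ifelse(is.na(sils$sub_hi[, 5]), NA, 55)
  expect_error(carve_slicewise(sils, n_min = 8, min_contrib = 1,
                               miss_frac = 0),
               "reconstruction failure")
})
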