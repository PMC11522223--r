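# kinematics module: period estimation, alignment, angle assignment

test_that("the period is recovered to sub-frame precision", {
  fx <- small_worm_fixture()
  expect_lt(abs(fx$est$period_frames - 24), 0.5)
  expect_gte(fx$est$peak_score, 0.6)
})

test_that("a non-integer period is refined by parabolic interpolation", {
  cond <- small_embryo_conditions(seed = 2)
  ph <- build_phantom(cond$spec, 0.5)
  rs <- cond$rspec
  rs$n_frames <- 60
  rs$period_frames <- 24.5
  rnd <- render_stack(ph, rs)
  est <- estimate_period(enhance(rnd$stack))
  expect_lt(abs(est$period_frames - 24.5), 0.5)
})

test_that("NCC is invariant to intensity scaling and offsets", {
  fx <- small_worm_fixture()
  scaled <- fx$enh
  scaled$frames <- 0.4 * scaled$frames + 0.21
  est2 <- estimate_period(scaled)
  expect_equal(est2$period_frames, fx$est$period_frames, tolerance = 1e-9)
})

test_that("static or degenerate stacks are rejected", {
  const <- image_stack(array(0.5, c(24, 24, 30)), 1)
  expect_error(estimate_period(const), "no reliable rotation")
  # identical (but non-constant) frames: ambiguous lag
  one <- matrix(runif(24 * 24), 24)
  ident <- image_stack(array(rep(one, 30), c(24, 24, 30)), 1)
  expect_error(estimate_period(ident), "no reliable rotation")
  expect_error(estimate_period(small_worm_fixture()$enh, min_lag = 2),
               "min_lag")
})

test_that("alignment recovers drift and preserves shape oscillation", {
  # zero drift: offsets are all (0, 0) within half a pixel
  fx <- small_worm_fixture()
  expect_lte(max(abs(fx$sils$offsets)), 1)

  # constant drift of 1 px/frame in x is undone frame by frame
  cond <- small_worm_conditions(seed = 8, drift = c(0.5, 0))
  cond$rspec$dim <- c(48, 192)
  ph <- build_phantom(cond$spec, 1)
  rnd <- render_stack(ph, cond$rspec)
  sils <- segment(enhance(rnd$stack))
  est <- estimate_period(enhance(rnd$stack))
  sils <- align_frames(sils, est$period_frames)
  i <- seq_len(dim(sils$masks)[3])
  slope <- stats::coef(stats::lm(sils$offsets[, "dx"] ~ i))[2]
  expect_lt(abs(slope + 0.5), 0.06) # recovered dx ~ -drift per frame
  resid <- sils$offsets[, "dx"] + 0.5 * (i - 1)
  expect_lt(max(abs(resid - mean(resid))), 1.6)

  # re-alignment is a fixed point
  again <- align_frames(sils, est$period_frames)
  expect_lte(max(abs(again$offsets)), 1)
})

test_that("angle assignment follows the uniform-rotation law", {
  est <- structure(list(period_frames = 64,
                        angles_rad = (2 * pi * (0:95) / 64) %% (2 * pi),
                        similarity = data.frame(), peak_score = 1,
                        ref_frame = 1L), class = "rotation_estimate")
  sils <- ideal_sils(96, rep(10, 64))
  sils$angles_rad <- rep(NA_real_, 96)
  sils$selected <- rep(FALSE, 96)
  sils$failed <- rep(FALSE, 96)
  out <- assign_angles(est, sils)
  expect_equal(out$angles_rad[17], pi / 2) # frame 16 steps past the ref
  expect_equal(sum(out$selected), 64)
  expect_true(all(out$angles_rad[out$selected] < 2 * pi))

  # non-integer period bookkeeping: frame ref+48 gets 2*pi*48/48.5
  est$period_frames <- 48.5
  out2 <- assign_angles(est, sils)
  expect_equal(out2$angles_rad[49], 2 * pi * 48 / 48.5)
  expect_equal(sum(out2$selected), 49) # ceil(48.5) frames, all below 2*pi

  # too few usable frames aborts
  sils$failed[] <- TRUE
  sils$failed[1:5] <- FALSE
  expect_error(assign_angles(est, sils), "usable frames")
})

test_that("assigned angles match the generator's angle trace", {
  fx <- small_worm_fixture()
  sel <- which(fx$sils$selected)
  tol <- 2 * pi * 0.5 / fx$cond$rspec$period_frames
  err <- abs(fx$sils$angles_rad[sel] - fx$rnd$angles_rad[sel])
  err <- pmin(err, abs(2 * pi - err))
  expect_lt(max(err), tol)
})
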