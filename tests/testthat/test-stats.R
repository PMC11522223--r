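# stats module: two-group t tests and PCA-based classification

test_that("the pooled t statistic matches textbook arithmetic exactly", {
  records <- data.frame(strain = rep(c("A", "B"), each = 3),
                        length_um = c(1, 2, 3, 4, 6, 8))
  cc <- compare_groups(records, "length_um", "A", "B")
  # hand computation: means 2 and 6, variances 1 and 4,
  # sp^2 = (2*1 + 2*4)/4 = 2.5, t = -4 / sqrt(2.5 * 2/3)
  t_hand <- -4 / sqrt(2.5 * (1 / 3 + 1 / 3))
  expect_equal(cc$t, t_hand, tolerance = 1e-12)
  expect_equal(cc$df, 4)
  expect_equal(cc$p, 2 * stats::pt(t_hand, 4), tolerance = 1e-12)
  expect_true(cc$significant) # p ~ 0.036 < 0.05
})

test_that("identical groups give t = 0, p = 1; separation is detected", {
  records <- data.frame(strain = rep(c("A", "B"), each = 3),
                        m = c(1, 2, 3, 1, 2, 3))
  cc <- compare_groups(records, "m", "A", "B")
  expect_equal(cc$t, 0)
  expect_equal(cc$p, 1)
  expect_false(cc$significant)

  shifted <- data.frame(strain = rep(c("A", "B"), each = 3),
                        m = c(1, 2, 3, 11, 12, 13))
  expect_lt(compare_groups(shifted, "m", "A", "B")$p, 0.05)

  degenerate <- data.frame(strain = rep(c("A", "B"), each = 3),
                           m = c(2, 2, 2, 2, 2, 2))
  expect_error(compare_groups(degenerate, "m", "A", "B"), "pooled variance")
  expect_error(compare_groups(records, "m", "A", "B", welch = FALSE,
                              group_col = "missing"), "missing")
})

test_that("empirical power matches the noncentral-t closed form", {
  n <- 15; delta <- 1; reps <- 1000; alpha <- 0.05
  hits <- with_seed_local(20240917, {
    sum(vapply(seq_len(reps), function(r) {
      a <- rnorm(n); b <- rnorm(n, delta)
      t.test(a, b, var.equal = TRUE)$p.value < alpha
    }, logical(1)))
  })
  power_hat <- hits / reps
  power_ref <- stats::power.t.test(n = n, delta = delta, sd = 1,
                                   sig.level = alpha)$power
  expect_lt(abs(power_hat - power_ref), 0.03)
})

test_that("well-separated clusters classify perfectly; shuffles are chance", {
  means <- rbind(A = c(100, 10, 5, 2, 1), B = c(150, 20, 10, 4, 2))
  sds <- rbind(c(2, 0.4, 0.2, 0.08, 0.04)) # ~5 SD separations
  rec <- simulate_morphometrics(c(A = 12, B = 12), means, sds, seed = 3)
  rep2 <- classify(rec, method = "pca_lr", seed = 1)
  expect_equal(rep2$accuracy, 1)
  expect_equal(rep2$correct, 24)

  shuffled <- rec
  shuffled$strain <- with_seed_local(11, sample(shuffled$strain))
  racc <- classify(shuffled, method = "pca_lr", seed = 1)$cv_accuracy
  expect_lt(abs(racc - 0.5), 0.1 + 1e-9)
})

test_that("four synthetic strains separate like the adult cohorts", {
  rec <- simulate_strain_cohort(seed = 1)
  expect_equal(nrow(rec), 62)
  rep4 <- classify(rec, method = "pca_svm", seed = 1)
  expect_gte(rep4$accuracy, 60 / 62) # at least 60-of-62-style separation
  expect_equal(sum(rep4$confusion), 62)
  expect_equal(unname(rowSums(rep4$confusion)),
               unname(as.vector(table(rec$strain)))) # row sums = class sizes
})

test_that("PCA components are orthonormal and folds shrink with warning", {
  rec <- simulate_strain_cohort(seed = 2)
  X <- scale(as.matrix(rec[, c("surface_area_um2", "volume_um3", "length_um",
                               "max_width_um", "ratio")]))
  pc <- prcomp(X, center = FALSE)
  expect_equal(crossprod(pc$rotation), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)

  tiny <- rec[rec$strain %in% c("ref", "mutA"), ][c(1:4, 17:20), ]
  expect_warning(classify(tiny, method = "pca_lr", folds = 5, seed = 1),
                 "reducing folds")
  expect_error(classify(rec, method = "pca_lr", seed = 1), "2 classes")
})

test_that("BH adjustment is available but off by default", {
  rec <- simulate_strain_cohort(seed = 3)
  raw <- adjust_comparisons(rec, "ref", "mutAB")
  expect_false("p_adj" %in% names(raw))
  adj <- adjust_comparisons(rec, "ref", "mutAB", bh = TRUE)
  expect_true(all(adj$p_adj >= adj$p - 1e-15))
})
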