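## stats module: per-metric two-group comparisons (two-tailed Student's t,
## pooled variance, alpha = 0.05) and PCA-based strain classification
## (logistic regression for two classes, SVM for several) on the five-metric
## vectors.

#' Two-group comparison of one morphometric metric
#'
#' Two-tailed two-sample t test; pooled-variance (Student's) by default,
#' Welch behind a flag. Group summaries are reported as mean +/- SD. No
#' multiple-testing correction is applied by default (raw p-values);
#' Benjamini-Hochberg is available via [adjust_comparisons()].
#'
#' @param records data.frame of morphometric records.
#' @param metric column name of the metric to compare.
#' @param group_a,group_b the two group labels.
#' @param group_col column holding group labels (default `"strain"`).
#' @param welch use Welch's unequal-variance t test instead of Student's?
#' @param alpha significance level for the flag.
#' @return a `group_comparison`: metric, groups, per-group n/mean/sd,
#'   `t`, `df`, `p`, `significant`.
#' @export
compare_groups <- function(records, metric, group_a, group_b,
                           group_col = "strain", welch = FALSE, alpha = 0.05) {
  if (!metric %in% names(records)) stopf("no column '%s' in records", metric)
  if (!group_col %in% names(records))
    stopf("no grouping column '%s' in records", group_col)
  xa <- records[[metric]][records[[group_col]] == group_a]
  xb <- records[[metric]][records[[group_col]] == group_b]
  if (length(xa) < 2 || length(xb) < 2)
    stopf("both groups need n >= 2 (have %d and %d)", length(xa), length(xb))
  if (sd(xa) == 0 && sd(xb) == 0)
    stopf("zero pooled variance: t statistic undefined")
  tt <- t.test(xa, xb, var.equal = !welch)
  structure(list(metric = metric, groups = c(group_a, group_b),
                 n = c(length(xa), length(xb)),
                 mean = c(mean(xa), mean(xb)), sd = c(sd(xa), sd(xb)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, significant = tt$p.value < alpha,
                 alpha = alpha, welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s %.4g +/- %.3g (n=%d) vs %s %.4g +/- %.3g (n=%d)\n",
              x$metric, x$groups[1], x$mean[1], x$sd[1], x$n[1],
              x$groups[2], x$mean[2], x$sd[2], x$n[2]))
  cat(sprintf("  t = %.4g, df = %.4g, two-tailed p = %.4g%s\n", x$t, x$df, x$p,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha) else ""))
  invisible(x)
}

#' Tabulate comparisons for every metric, optionally BH-adjusted
#' @param records morphometric records.
#' @param group_a,group_b,group_col as in [compare_groups()].
#' @param metrics metric columns to test.
#' @param bh apply Benjamini-Hochberg adjustment (off by default)?
#' @return data.frame of per-metric comparisons.
#' @export
adjust_comparisons <- function(records, group_a, group_b, group_col = "strain",
                               metrics = c("surface_area_um2", "volume_um3",
                                           "length_um", "max_width_um", "ratio"),
                               bh = FALSE) {
  rows <- lapply(metrics, function(m) {
    cc <- compare_groups(records, m, group_a, group_b, group_col)
    data.frame(metric = m, t = cc$t, p = cc$p)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' PCA-based classification of strains from the five metrics
#'
#' Metrics are z-scored, projected on the leading principal components, and
#' classified by logistic regression (two classes) or an SVM (two or more;
#' RBF kernel by default, linear behind a flag). Accuracy is reported both
#' by resubstitution (region counts as in decision-boundary plots) and by
#' stratified cross-validation.
#'
#' @param records morphometric records.
#' @param label_col column holding the class labels.
#' @param method `"pca_lr"` or `"pca_svm"`.
#' @param n_components leading principal components retained (default 2).
#' @param folds stratified CV folds; reduced with a warning when a class
#'   has fewer members.
#' @param kernel SVM kernel (`"radial"` default, `"linear"` available).
#' @param metrics feature columns.
#' @param seed seed for fold assignment.
#' @return a `classification_report`: method, n_components, `confusion`
#'   (resubstitution), `accuracy` (resubstitution), `cv_accuracy`,
#'   `per_class`, `correct`/`total`.
#' @export
classify <- function(records, label_col = "strain",
                     method = c("pca_lr", "pca_svm"), n_components = 2,
                     folds = 5, kernel = "radial",
                     metrics = c("surface_area_um2", "volume_um3", "length_um",
                                 "max_width_um", "ratio"),
                     seed = 1L) {
  method <- match.arg(method)
  y <- factor(records[[label_col]])
  if (nlevels(y) < 2) stopf("need >= 2 classes")
  if (any(table(y) < 3)) stopf("every class needs n >= 3")
  X <- scale(as.matrix(records[, metrics]))
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  S <- pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
  dat <- data.frame(S, y = y)

  fit_predict <- function(train, test) {
    if (method == "pca_lr") {
      if (nlevels(y) != 2)
        stopf("pca_lr requires exactly 2 classes; use pca_svm")
      fit <- glm(y ~ ., data = dat[train, , drop = FALSE], family = binomial())
      p <- predict(fit, dat[test, , drop = FALSE], type = "response")
      factor(levels(y)[1 + (p > 0.5)], levels = levels(y))
    } else {
      fit <- e1071::svm(y ~ ., data = dat[train, , drop = FALSE],
                        kernel = kernel, type = "C-classification")
      predict(fit, dat[test, , drop = FALSE])
    }
  }

  all_idx <- seq_len(nrow(dat))
  resub <- fit_predict(all_idx, all_idx)
  confusion <- table(truth = y, predicted = resub)
  accuracy <- mean(resub == y)

  min_class <- min(table(y))
  if (min_class < folds) {
    warnf("smallest class (n=%d) < folds (%d); reducing folds", min_class, folds)
    folds <- max(2L, min_class)
  }
  fold_id <- integer(nrow(dat))
  with_seed(seed, for (lv in levels(y)) {
    idx <- which(y == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  })
  cv_pred <- factor(rep(NA_character_, nrow(dat)), levels = levels(y))
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    cv_pred[test] <- fit_predict(which(fold_id != f), test)
  }
  cv_accuracy <- mean(cv_pred == y)

  structure(list(method = method, n_components = n_components,
                 confusion = confusion, accuracy = accuracy,
                 cv_accuracy = cv_accuracy,
                 per_class = diag(prop.table(confusion, 1)),
                 correct = sum(diag(confusion)), total = length(y),
                 folds = folds, scores = S, labels = y),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s on %d PCs: %d/%d correct (%.1f%%), CV %.1f%%\n",
              x$method, x$n_components, x$correct, x$total,
              100 * x$accuracy, 100 * x$cv_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Simulate morphometric records for several strains
#'
#' Draws per-specimen five-metric vectors from independent normals with
#' per-strain means and SDs; a simulation harness for the group-statistics
#' stage (it does not run the imaging pipeline).
#'
#' @param n_per_class integer vector of class sizes (named by strain).
#' @param means matrix (classes x 5) of metric means; rownames are strains.
#' @param sds matrix like `means` with SDs (or a single row recycled).
#' @param stage `"adult"` or `"embryo"` annotation.
#' @param seed integer seed.
#' @return a morphometric-record data.frame.
#' @export
simulate_morphometrics <- function(n_per_class, means, sds,
                                   stage = "adult", seed = 1L) {
  metrics <- c("surface_area_um2", "volume_um3", "length_um",
               "max_width_um", "ratio")
  if (is.null(rownames(means))) rownames(means) <- names(n_per_class)
  if (nrow(sds) == 1) sds <- sds[rep(1, nrow(means)), , drop = FALSE]
  with_seed(seed, {
    rows <- lapply(seq_along(n_per_class), function(k) {
      n <- n_per_class[k]
      vals <- vapply(1:5, function(j) rnorm(n, means[k, j], sds[k, j]),
                     numeric(n))
      df <- as.data.frame(vals)
      names(df) <- metrics
      cbind(data.frame(sample_id = sprintf("%s_%02d", rownames(means)[k],
                                           seq_len(n)),
                       strain = rownames(means)[k], stage = stage),
            df, qc_mean_iou = NA_real_)
    })
    do.call(rbind, rows)
  })
}

#' Archetypal four-strain adult cohort for the classification demo
#'
#' Four synthetic strains (a wild-type-like reference, two single-mutant-like
#' strains and a double-mutant-like strain) with distinct five-metric mean
#' vectors and realistic coefficients of variation, sized 15-16 specimens per
#' strain. The separations are designed to the qualitative structure of
#' mutant phenotyping experiments (clearly separable adults); they are not a
#' reproduction of any particular animals.
#'
#' @param seed integer seed.
#' @return a morphometric-record data.frame (62 rows).
#' @export
simulate_strain_cohort <- function(seed = 1L) {
  strains <- c("ref", "mutA", "mutB", "mutAB")
  means <- rbind(
    ref   = c(156000, 3.4e6, 1180, 62, 19.0),
    mutA  = c(122000, 2.3e6,  980, 55, 17.8),
    mutB  = c(138000, 3.1e6, 1050, 64, 16.4),
    mutAB = c(101000, 1.9e6,  860, 58, 14.8))
  sds <- rbind(c(6500, 0.16e6, 38, 2.4, 0.55))
  simulate_morphometrics(c(ref = 16, mutA = 15, mutB = 16, mutAB = 15),
                         means, sds, stage = "adult", seed = seed)
}

#' Write a classification report as JSON
#' @param report a `classification_report`.
#' @param path output file.
#' @export
write_classification_json <- function(report, path) {
  jsonlite::write_json(
    list(method = report$method, n_components = report$n_components,
         accuracy = report$accuracy, cv_accuracy = report$cv_accuracy,
         correct = report$correct, total = report$total,
         confusion = as.data.frame(report$confusion)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
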