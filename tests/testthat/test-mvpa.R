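test_that("F-scores match hand evaluation, including degenerate features", {
  # positive (2, 4), negative (0, 2): numerator 2, denominator 4
  x1 <- matrix(c(2, 4, 0, 2), 4, 1)
  y <- c("patient", "patient", "control", "control")
  expect_equal(f_score(x1, y)$scores, 0.5)
  # class means equal the grand mean -> zero numerator -> 0
  x2 <- matrix(c(1, 3, 3, 1), 4, 1)
  expect_equal(f_score(x2, y)$scores, 0)
  # constant, different classes -> +Inf sentinel ranked first
  x3 <- cbind(c(1, 1, 0, 0), c(2, 4, 0, 2))
  fs <- f_score(x3, y)
  expect_identical(fs$scores[1], Inf)
  expect_identical(fs$ranking[1], 1L)
  # constant identical classes -> both terms zero -> 0
  x4 <- matrix(c(5, 5, 5, 5), 4, 1)
  expect_equal(f_score(x4, y)$scores, 0)
  expect_error(f_score(x1, c("patient", "control", "control", "control")), "at least 2")
})

test_that("F-score ranking is descending with ascending-index tie-break", {
  x <- cbind(c(2, 4, 0, 2), c(0, 2, 2, 4), c(9, 9.1, 0, 0.1))
  y <- c("patient", "patient", "control", "control")
  fs <- f_score(x, y)
  expect_equal(fs$scores[1], fs$scores[2]) # symmetric features tie
  expect_lt(which(fs$ranking == 1), which(fs$ranking == 2)) # index breaks the tie
  expect_identical(fs$ranking[1], 3L) # clearly strongest feature first
  # duplicating every subject rescales all scores equally: ranking unchanged
  fs2 <- f_score(rbind(x, x), c(y, y))
  expect_identical(fs$ranking, fs2$ranking)
})

test_that("LOOCV matches an independent fold-by-fold reference implementation", {
  set.seed(19)
  x <- matrix(rnorm(14 * 30), 14)
  x[1:7, 1:3] <- x[1:7, 1:3] + 1.5
  y <- rep(c("patient", "control"), each = 7)
  for (k in c(1, 5, 30)) {
    got <- loocv_classify(x, y, k)
    want <- oracle_naive_loocv(x, y, k)
    expect_identical(got$predicted_label, want$predicted_label)
    expect_equal(got$decision_score, want$decision_score, tolerance = 1e-8)
  }
})

test_that("a perfectly separating feature yields 100% LOOCV accuracy", {
  set.seed(23)
  x <- cbind(c(rnorm(8, 10, 0.5), rnorm(8, -10, 0.5)), matrix(rnorm(16 * 20), 16))
  y <- rep(c("patient", "control"), each = 8)
  for (k in c(1, 5)) {
    rec <- loocv_classify(x, y, k)
    expect_equal(mean(rec$predicted_label == rec$true_label), 1)
  }
  # patients receive positive decision scores in the separable case
  rec <- loocv_classify(x, y, 1)
  expect_true(all(rec$decision_score[y == "patient"] > 0))
  expect_true(all(rec$decision_score[y == "control"] < 0))
})

test_that("training-fold-only feature ranking does not leak the held-out subject", {
  x <- withr::with_seed(101, matrix(rnorm(40 * 500), 40))
  y <- rep(c("patient", "control"), each = 20)
  proper <- 100 * mean({
    r <- loocv_classify(x, y, 10)
    r$predicted_label == r$true_label
  })
  leaked <- leaky_loocv_accuracy(x, y, 10)
  # on pure noise, leaking the test subject into feature selection inflates
  # accuracy far above chance; the proper estimate stays near 50%
  expect_gt(leaked, proper + 10)
  expect_lt(abs(proper - 50), 20)
})

test_that("classification metrics reproduce the confusion-matrix formulas", {
  rec <- data.frame(
    true_label = c(rep("patient", 5), rep("control", 3)),
    predicted_label = c(
      "patient", "patient", "patient", "control", "control",
      "control", "control", "patient"
    )
  )
  m <- classification_metrics(rec)
  expect_equal(m$accuracy, 62.5)
  expect_equal(m$sensitivity, 60)
  expect_equal(m$specificity, 200 / 3)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(3, 2, 1, 2))
  # all predicted patient: sensitivity 100, specificity 0
  rec2 <- rec
  rec2$predicted_label <- "patient"
  m2 <- classification_metrics(rec2)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)
  # all correct
  rec3 <- rec
  rec3$predicted_label <- rec3$true_label
  expect_equal(classification_metrics(rec3)$accuracy, 100)
  expect_error(
    classification_metrics(data.frame(
      true_label = c("patient", "patient"), predicted_label = c("patient", "patient")
    )),
    "specificity"
  )
})

test_that("ROC/AUC equals the brute-force pairwise computation", {
  rec <- data.frame(
    true_label = c("patient", "patient", "control", "control"),
    decision_score = c(2, 3, 1, 2.5)
  )
  out <- roc_curve_auc(rec)
  expect_equal(out$auc, 0.75)
  # perfectly separated
  rec2 <- data.frame(
    true_label = rep(c("patient", "control"), each = 3),
    decision_score = c(4, 5, 6, 1, 2, 3)
  )
  expect_equal(roc_curve_auc(rec2)$auc, 1)
  # random toys, including ties: exact equality with pairwise enumeration
  for (s in 1:20) {
    rec3 <- withr::with_seed(s, data.frame(
      true_label = sample(rep(c("patient", "control"), times = c(6, 5))),
      decision_score = sample(seq(-1, 1, by = 0.25), 11, replace = TRUE)
    ))
    expect_equal(
      roc_curve_auc(rec3)$auc,
      oracle_pairwise_auc(rec3$decision_score, rec3$true_label == "patient")
    )
  }
  # ROC endpoints
  expect_equal(out$points$fpr[1], 0)
  expect_equal(out$points$tpr[1], 0)
  expect_equal(out$points$fpr[nrow(out$points)], 1)
  expect_equal(out$points$tpr[nrow(out$points)], 1)
  # constant scores warn and fall back to 0.5
  rec4 <- data.frame(
    true_label = c("patient", "control"),
    decision_score = c(1, 1)
  )
  expect_warning(out4 <- roc_curve_auc(rec4), "identical")
  expect_equal(out4$auc, 0.5)
})

test_that("the feature-count grid covers [start, n_features) and the sweep picks the smallest argmax", {
  g <- feature_count_grid(24531, 20, 20)
  expect_equal(g[1], 20)
  expect_equal(g[length(g)], 24520)
  expect_equal(g[207], 4140)
  expect_error(feature_count_grid(10, 20, 20), "empty")
  set.seed(41)
  # every feature is (a slightly perturbed copy of) a separating signal, so
  # LOOCV accuracy is 100% at every grid value and ties must resolve to the
  # smallest feature count
  signal <- c(rnorm(6, 10, 0.2), rnorm(6, -10, 0.2))
  x <- matrix(rep(signal, 20), 12) + matrix(rnorm(12 * 20, 0, 0.01), 12)
  y <- rep(c("patient", "control"), each = 6)
  res <- sweep_feature_counts(x, y, grid_start = 2, grid_step = 4)
  expect_equal(res$accuracy_by_feature_count$n_features, seq(2, 19, by = 4))
  # separable at every k here, so the smallest grid value must be selected
  expect_true(all(res$accuracy_by_feature_count$accuracy == 100))
  expect_equal(res$selected_feature_count, 2)
  # stored summary metrics are recomputable from the per-subject records
  m <- classification_metrics(res$records)
  expect_identical(res$accuracy, m$accuracy)
  expect_identical(res$sensitivity, m$sensitivity)
  expect_identical(res$specificity, m$specificity)
  expect_equal(res$auc, roc_curve_auc(res$records)$auc)
})

test_that("permutation p honors the strict exceedance definition and the seed", {
  x <- withr::with_seed(3, matrix(rnorm(16 * 40), 16))
  y <- rep(c("patient", "control"), each = 8)
  # observed accuracy below any possible null -> p = 1
  p_lo <- permutation_test(x, y, 5,
    n_permutations = 20, seed = 2,
    observed_accuracy = -1
  )
  expect_equal(p_lo$p_value, 1)
  # observed accuracy above any possible null -> p = 0
  p_hi <- permutation_test(x, y, 5,
    n_permutations = 20, seed = 2,
    observed_accuracy = 101
  )
  expect_equal(p_hi$p_value, 0)
  expect_equal(
    p_lo$p_value,
    sum(p_lo$null_accuracies > p_lo$observed_accuracy) / p_lo$n_permutations
  )
  # same seed -> identical null distribution; different seed -> different
  p_a <- permutation_test(x, y, 5, n_permutations = 10, seed = 7, observed_accuracy = 50)
  p_b <- permutation_test(x, y, 5, n_permutations = 10, seed = 7, observed_accuracy = 50)
  expect_identical(p_a$null_accuracies, p_b$null_accuracies)
  p_c <- permutation_test(x, y, 5, n_permutations = 10, seed = 8, observed_accuracy = 50)
  expect_false(identical(p_a$null_accuracies, p_c$null_accuracies))
})

test_that("strongly separable synthetic groups reach significance", {
  d <- generate_task_design(30, 10, seed = 17)
  cfg <- simulation_config(
    n_per_group = 10, n_rois = 12, n_trials = 30, n_modules = 2,
    within_r = 0.5, between_r = 0.1,
    group_delta_within = -0.3, group_delta_between = 0, seed = 17
  )
  cohort <- generate_group_beta_series(cfg, d)
  groups <- vapply(cohort, `[[`, "", "group")
  feats <- t(vapply(
    cohort,
    function(s) vectorize_upper_triangle(beta_series_correlation(s$beta_series, NULL))$values,
    numeric(66)
  ))
  rec <- loocv_classify(feats, groups, 20)
  acc <- 100 * mean(rec$predicted_label == rec$true_label)
  expect_gt(acc, 60)
  p <- permutation_test(feats, groups, 20,
    n_permutations = 99, seed = 17,
    observed_accuracy = acc
  )
  expect_lt(p$p_value, 0.05)
})
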