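test_that("cohort generation is bit-identical under the same seed", {
  d <- generate_task_design(24, 8, seed = 5)
  cfg <- simulation_config(n_per_group = 3, n_rois = 10, n_trials = 24, seed = 5)
  a <- generate_group_beta_series(cfg, d)
  b <- generate_group_beta_series(cfg, d)
  expect_identical(a, b)
  cfg2 <- simulation_config(n_per_group = 3, n_rois = 10, n_trials = 24, seed = 6)
  c <- generate_group_beta_series(cfg2, d)
  expect_false(identical(
    a[[1]]$beta_series$values,
    c[[1]]$beta_series$values
  ))
})

test_that("empirical correlations recover the target block structure", {
  n_trials <- 500
  d <- generate_task_design(n_trials, 100, seed = 2)
  cfg <- simulation_config(
    n_per_group = 3, n_rois = 20, n_trials = n_trials, n_modules = 2,
    within_r = 0.5, between_r = 0.1,
    group_delta_within = 0, group_delta_between = 0, seed = 2
  )
  cohort <- generate_group_beta_series(cfg, d)
  modules <- cfg$module_assignment
  same <- outer(modules, modules, "==")
  within_mask <- same & upper.tri(same)
  between_mask <- !same & upper.tri(same)
  rs <- lapply(cohort, function(s) cor(s$beta_series$values))
  mean_within <- mean(vapply(rs, function(r) mean(r[within_mask]), 0))
  mean_between <- mean(vapply(rs, function(r) mean(r[between_mask]), 0))
  expect_lt(abs(mean_within - 0.5), 0.05)
  expect_lt(abs(mean_between - 0.1), 0.05)
})

test_that("the patient-group correlation offset is recovered empirically", {
  n_trials <- 500
  d <- generate_task_design(n_trials, 100, seed = 3)
  cfg <- simulation_config(
    n_per_group = 4, n_rois = 20, n_trials = n_trials, n_modules = 2,
    within_r = 0.5, between_r = 0.1,
    group_delta_within = -0.2, group_delta_between = 0, seed = 3
  )
  cohort <- generate_group_beta_series(cfg, d)
  modules <- cfg$module_assignment
  within_mask <- outer(modules, modules, "==") & upper.tri(diag(20))
  groups <- vapply(cohort, `[[`, "", "group")
  mean_within <- function(grp) {
    mean(vapply(
      cohort[groups == grp],
      function(s) mean(cor(s$beta_series$values)[within_mask]), 0
    ))
  }
  expect_lt(abs(mean_within("control") - mean_within("patient") - 0.2), 0.05)
})

test_that("a non-positive-definite block target is repaired rather than fatal", {
  d <- generate_task_design(30, 10, seed = 4)
  # strongly negative between-community correlation over many communities is
  # not a valid covariance; the generator must clip eigenvalues and proceed
  cfg <- simulation_config(
    n_per_group = 2, n_rois = 12, n_trials = 30, n_modules = 4,
    within_r = 0.6, between_r = -0.4,
    group_delta_within = 0, group_delta_between = 0, seed = 4
  )
  cohort <- generate_group_beta_series(cfg, d)
  expect_true(all(is.finite(cohort[[1]]$beta_series$values)))
})

test_that("behavioural group effects point the expected way", {
  d <- generate_task_design(24, 8, seed = 6)
  cfg <- simulation_config(n_per_group = 25, n_rois = 4, n_trials = 24, seed = 6)
  cohort <- generate_group_beta_series(cfg, d)
  groups <- vapply(cohort, `[[`, "", "group")
  rt <- vapply(cohort, function(s) s$behavior$mean_rt_ms, 0)
  acc <- vapply(cohort, function(s) s$behavior$accuracy_fraction, 0)
  expect_gt(mean(rt[groups == "patient"]), mean(rt[groups == "control"]))
  expect_lt(mean(acc[groups == "patient"]), mean(acc[groups == "control"]))
  expect_true(all(acc >= 0 & acc <= 1))
})

test_that("BOLD synthesis reduces to the HRF for a single noiseless event", {
  d <- generate_task_design(1, 0, tr_s = 2, iti_s = 20, jitter_s = 0, seed = 1)
  sim <- generate_bold_timeseries(d, matrix(1, 1, 1), noise_sd = 0, seed = 2)
  y <- sim$timeseries[, 1]
  onset_scan <- floor(d$trials$onset_s[1] / d$tr_s) + 1
  expect_equal(max(abs(y[seq_len(onset_scan - 1)])), 0) # silent before onset
  # the response equals the double-gamma kernel (evaluated directly here)
  # shifted to the onset, scaled so the continuous-time peak is 1
  dg <- function(t) dgamma(t, 6) - dgamma(t, 16) / 6
  t_rel <- (seq_len(17) - 1) * d$tr_s
  expected <- dg(t_rel) / max(dg(seq(0, 32, by = 0.01)))
  expect_equal(unname(y[onset_scan + seq_len(17) - 1]), expected, tolerance = 1e-3)
  peak_t <- (which.max(y) - 1) * d$tr_s - d$trials$onset_s[1]
  expect_true(peak_t >= 4 && peak_t <= 6)
  # zero amplitudes -> exactly zero series (leakage disabled by default)
  sim0 <- generate_bold_timeseries(d, matrix(0, 1, 1), noise_sd = 0, seed = 2)
  expect_equal(max(abs(sim0$timeseries)), 0)
  expect_named(
    sim$confounds,
    c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z", "white_matter", "csf")
  )
})
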