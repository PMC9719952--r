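#' Configuration for the two-group synthetic cohort generator
#'
#' Describes the statistical structure of a simulated case-control cohort of
#' trial-wise regional responses. Regions are partitioned into communities
#' (functional modules); within each subject the trial-by-trial responses are
#' multivariate normal with correlation `within_r` between regions of the
#' same community and `between_r` otherwise. The patient group's target
#' correlations are offset by `group_delta_within` / `group_delta_between`,
#' giving a controllable group difference in network structure. Behavioural
#' measures (mean response time, accuracy) are drawn with a group effect in
#' the direction typically reported for schizophrenia (slower, less
#' accurate).
#'
#' Defaults emulate the cohort structure of a two-site case-control
#' task-switching study: 46 subjects per group, 222 regions in 10 modules,
#' a 96-trial run, moderate within-module coupling (r = 0.4) against a weak
#' between-module background (r = 0.1), and patients showing modestly
#' reduced coupling.
#'
#' @param n_per_group Subjects per group.
#' @param n_rois Number of regions.
#' @param n_trials Trials per subject (must match the design used).
#' @param module_assignment Integer/character vector of length `n_rois`
#'   assigning each region to a community; default splits regions into
#'   `n_modules` contiguous, near-equal communities.
#' @param n_modules Number of communities for the default assignment.
#' @param within_r,between_r Target Pearson correlations within / between
#'   communities (each in (-1, 1)).
#' @param group_delta_within,group_delta_between Additive offsets applied to
#'   the patient group's within-/between-community correlations.
#' @param noise_sd Amplitude standard deviation passed through to the BOLD
#'   generator when raw time series are simulated.
#' @param rt_control_ms,rt_sd_ms,rt_patient_shift_ms Behavioural response
#'   time model: control mean, common SD, and the patients' mean shift (ms).
#' @param acc_control_shape,acc_patient_shape Beta-distribution shape pairs
#'   for control and patient accuracy fractions.
#' @param seed Top-level integer seed; all cohort randomness derives from it.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 46, n_rois = 222, n_trials = 96,
                              module_assignment = NULL, n_modules = 10,
                              within_r = 0.4, between_r = 0.1,
                              group_delta_within = -0.1,
                              group_delta_between = -0.05,
                              noise_sd = 1,
                              rt_control_ms = 800, rt_sd_ms = 100,
                              rt_patient_shift_ms = 120,
                              acc_control_shape = c(38, 2),
                              acc_patient_shape = c(27, 3),
                              seed = 1L) {
  if (is.null(module_assignment)) {
    module_assignment <- sort(rep_len(seq_len(n_modules), n_rois))
  }
  if (length(module_assignment) != n_rois) {
    stop("module_assignment must have one entry per region", call. = FALSE)
  }
  rs <- c(
    within_r, between_r,
    within_r + group_delta_within, between_r + group_delta_between
  )
  if (any(rs <= -1) || any(rs >= 1)) {
    stop("all target correlations (including group offsets) must lie in (-1, 1)",
      call. = FALSE
    )
  }
  structure(
    list(
      n_per_group = n_per_group, n_rois = n_rois, n_trials = n_trials,
      module_assignment = module_assignment,
      within_r = within_r, between_r = between_r,
      group_delta_within = group_delta_within,
      group_delta_between = group_delta_between,
      noise_sd = noise_sd,
      rt_control_ms = rt_control_ms, rt_sd_ms = rt_sd_ms,
      rt_patient_shift_ms = rt_patient_shift_ms,
      acc_control_shape = acc_control_shape,
      acc_patient_shape = acc_patient_shape,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Block-structured target correlation matrix from a community assignment.
block_correlation <- function(module_assignment, within_r, between_r) {
  same <- outer(module_assignment, module_assignment, "==")
  r <- ifelse(same, within_r, between_r)
  diag(r) <- 1
  r
}

# Repair a slightly non-positive-semi-definite correlation matrix by
# clipping negative eigenvalues to a small floor and renormalising to unit
# diagonal. Errors if the result is still meaningfully non-PSD.
repair_psd <- function(r, floor = 1e-10, tol = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < 0) {
    vals <- pmax(e$values, floor)
    r <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(r))
    r <- r / tcrossprod(d)
    r <- (r + t(r)) / 2
    diag(r) <- 1
  }
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
    stop("target correlation matrix is not positive semi-definite after repair",
      call. = FALSE
    )
  }
  r
}

#' Generate a two-group cohort of trial-wise beta series
#'
#' Draws, for every subject in both groups, a trials-by-regions matrix of
#' zero-mean multivariate-normal single-trial response amplitudes whose
#' correlation follows the block (community) structure of the
#' [simulation_config()], with the patient group's within-/between-community
#' correlations offset by the configured group deltas. Behavioural summaries
#' (mean RT, accuracy) and small head-motion traces are attached to each
#' subject.
#'
#' @param config A [simulation_config()].
#' @param design A [generate_task_design()] design with
#'   `config$n_trials` trials.
#'
#' @return A list of subject records (class `subject_cohort`). Each record
#'   has `subject_id`, `group` (`"patient"` or `"control"`), `beta_series`
#'   (a [beta_series()] object), `behavior` (`mean_rt_ms`,
#'   `accuracy_fraction`) and `motion` (scans x 6 matrix: translations in mm,
#'   rotations in rad).
#' @export
#' @examples
#' cfg <- simulation_config(n_per_group = 4, n_rois = 12, n_trials = 24, seed = 7)
#' design <- generate_task_design(24, 8, seed = 7)
#' cohort <- generate_group_beta_series(cfg, design)
#' length(cohort) # 8 subjects
generate_group_beta_series <- function(config, design) {
  stopifnot(inherits(config, "simulation_config"), inherits(design, "trial_design"))
  if (n_design_trials(design) != config$n_trials) {
    stop("design has ", n_design_trials(design), " trials but config expects ",
      config$n_trials,
      call. = FALSE
    )
  }
  roi_labels <- sprintf("ROI%03d", seq_len(config$n_rois))
  targets <- list(
    control = repair_psd(block_correlation(
      config$module_assignment, config$within_r, config$between_r
    )),
    patient = repair_psd(block_correlation(
      config$module_assignment,
      config$within_r + config$group_delta_within,
      config$between_r + config$group_delta_between
    ))
  )
  chols <- lapply(targets, function(r) chol(r + diag(1e-9, nrow(r))))
  cohort <- list()
  for (group in c("control", "patient")) {
    up <- chols[[group]]
    for (k in seq_len(config$n_per_group)) {
      sid <- sprintf("sub-%s%02d", group, k)
      betas <- withr::with_seed(
        substream_seed(config$seed, paste0("betas_", group), k),
        matrix(stats::rnorm(config$n_trials * config$n_rois), config$n_trials) %*% up
      )
      colnames(betas) <- roi_labels
      behav <- withr::with_seed(
        substream_seed(config$seed, paste0("behavior_", group), k),
        {
          shift <- if (group == "patient") config$rt_patient_shift_ms else 0
          shp <- if (group == "patient") config$acc_patient_shape else config$acc_control_shape
          list(
            mean_rt_ms = stats::rnorm(1, config$rt_control_ms + shift, config$rt_sd_ms),
            accuracy_fraction = stats::rbeta(1, shp[1], shp[2])
          )
        }
      )
      motion <- withr::with_seed(
        substream_seed(config$seed, paste0("motion_", group), k),
        cbind(
          apply(matrix(stats::rnorm(design$n_scans * 3, 0, 0.02), ncol = 3), 2, cumsum),
          apply(matrix(stats::rnorm(design$n_scans * 3, 0, 5e-4), ncol = 3), 2, cumsum)
        )
      )
      colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
      cohort[[sid]] <- list(
        subject_id = sid,
        group = group,
        beta_series = beta_series(betas, design$trials$condition),
        behavior = behav,
        motion = motion
      )
    }
  }
  structure(cohort,
    class = "subject_cohort",
    config = config, module_assignment = config$module_assignment
  )
}

#' @export
print.subject_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, "", "group")
  cfg <- attr(x, "config")
  cat(
    "Synthetic cohort: ", sum(groups == "patient"), " patients + ",
    sum(groups == "control"), " controls, ", cfg$n_rois, " regions, ",
    cfg$n_trials, " trials\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate BOLD-like ROI time series from trial amplitudes
#'
#' Builds, for each region, the scan-resolution signal
#' `sum over trials of amplitude x HRF-convolved stick at the trial onset`,
#' optionally adds a leakage of the nuisance signals into the data, and adds
#' white Gaussian noise. Also generates a matching confound table (six
#' rigid-body motion parameters as random walks plus AR(1)-like white-matter
#' and CSF mean signals), so the least-squares-separate estimator can be
#' exercised end to end.
#'
#' @param design A [generate_task_design()] design.
#' @param true_amplitudes Trials x regions matrix of single-trial amplitudes.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   amplitude units.
#' @param seed Integer seed.
#' @param hrf An [hrf_model()]; defaults to the canonical model at the
#'   design's TR.
#' @param confound_leakage Scale of the leakage of confound signals into the
#'   data (0 disables leakage; the confound table is generated either way).
#'
#' @return List with `timeseries` (scans x regions matrix) and `confounds`
#'   (data frame: `trans_x`..`rot_z`, `white_matter`, `csf`).
#' @export
generate_bold_timeseries <- function(design, true_amplitudes, noise_sd = 1,
                                     seed = 1L, hrf = hrf_model(tr_s = design$tr_s),
                                     confound_leakage = 0) {
  stopifnot(inherits(design, "trial_design"))
  true_amplitudes <- as.matrix(true_amplitudes)
  n_trials <- n_design_trials(design)
  if (nrow(true_amplitudes) != n_trials) {
    stop("true_amplitudes must have one row per design trial", call. = FALSE)
  }
  n_scans <- design$n_scans
  onsets <- design$trials$onset_s
  if (any(onsets < 0) || any(onsets >= n_scans * design$tr_s)) {
    stop("trial onsets must fit inside the scanning run", call. = FALSE)
  }
  regressors <- vapply(
    onsets,
    function(o) convolve_events(o, n_scans, design$tr_s, hrf),
    numeric(n_scans)
  )
  signal <- regressors %*% true_amplitudes
  n_rois <- ncol(true_amplitudes)
  confounds <- withr::with_seed(substream_seed(seed, "confounds"), {
    motion <- cbind(
      apply(matrix(stats::rnorm(n_scans * 3, 0, 0.02), ncol = 3), 2, cumsum),
      apply(matrix(stats::rnorm(n_scans * 3, 0, 5e-4), ncol = 3), 2, cumsum)
    )
    wm <- as.numeric(stats::filter(stats::rnorm(n_scans), 0.9, method = "recursive"))
    csf <- as.numeric(stats::filter(stats::rnorm(n_scans), 0.9, method = "recursive"))
    data.frame(
      trans_x = motion[, 1], trans_y = motion[, 2], trans_z = motion[, 3],
      rot_x = motion[, 4], rot_y = motion[, 5], rot_z = motion[, 6],
      white_matter = wm, csf = csf
    )
  })
  if (confound_leakage != 0) {
    weights <- withr::with_seed(
      substream_seed(seed, "leakage"),
      matrix(stats::rnorm(ncol(confounds) * n_rois, 0, confound_leakage), ncol = n_rois)
    )
    signal <- signal + as.matrix(confounds) %*% weights
  }
  if (noise_sd > 0) {
    signal <- signal + withr::with_seed(
      substream_seed(seed, "noise"),
      matrix(stats::rnorm(n_scans * n_rois, 0, noise_sd), n_scans)
    )
  }
  colnames(signal) <- colnames(true_amplitudes)
  list(timeseries = signal, confounds = confounds)
}
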