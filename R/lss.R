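#' Beta series container
#'
#' A beta series is the trials x regions matrix of single-trial response
#' amplitude estimates together with the per-trial switch/repeat condition
#' labels it inherits from the task design.
#'
#' @param values Trials x regions numeric matrix.
#' @param condition_labels Character vector, one condition per trial.
#' @return An object of class `beta_series`.
#' @export
beta_series <- function(values, condition_labels) {
  values <- as.matrix(values)
  if (nrow(values) != length(condition_labels)) {
    stop("need one condition label per trial (row)", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("beta series values must be finite", call. = FALSE)
  }
  structure(
    list(values = values, condition_labels = as.character(condition_labels)),
    class = "beta_series"
  )
}

#' @export
print.beta_series <- function(x, ...) {
  cat(
    "Beta series: ", nrow(x$values), " trials x ", ncol(x$values),
    " regions (", paste(sprintf(
      "%d %s", table(x$condition_labels),
      names(table(x$condition_labels))
    ), collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Build the least-squares-separate design matrix for one trial
#'
#' The least-squares-separate (LSS) scheme fits one GLM per trial. Each GLM
#' has exactly two task regressors — an HRF-convolved stick (duration 0) at
#' the onset of the trial of interest, and a single regressor combining the
#' sticks of all remaining trials — followed by the confound columns
#' (unmodified) and an intercept. With the standard six motion parameters
#' plus white-matter and CSF means this yields an 11-column design.
#'
#' @param design A [generate_task_design()] design (onsets at cue
#'   presentation).
#' @param trial_index Which trial is the trial of interest (1-based).
#' @param confounds Data frame or matrix of nuisance regressors, one row per
#'   scan; `NULL` for a confound-free design.
#' @param n_scans Number of scans; defaults to the design's run length.
#' @param hrf An [hrf_model()].
#' @return Numeric matrix with named columns `trial_of_interest`,
#'   `other_trials`, the confound columns, and `intercept`.
#' @export
build_lss_design <- function(design, trial_index, confounds = NULL,
                             n_scans = design$n_scans,
                             hrf = hrf_model(tr_s = design$tr_s)) {
  n_trials <- n_design_trials(design)
  if (trial_index < 1L || trial_index > n_trials) {
    stop("trial_index must lie in [1, ", n_trials, "]", call. = FALSE)
  }
  onsets <- design$trials$onset_s
  own <- convolve_events(onsets[trial_index], n_scans, design$tr_s, hrf)
  others <- convolve_events(onsets[-trial_index], n_scans, design$tr_s, hrf)
  x <- cbind(trial_of_interest = own, other_trials = others)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_scans) {
      stop("confounds must have one row per scan", call. = FALSE)
    }
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- sprintf("confound_%d", seq_len(ncol(confounds)))
    }
    x <- cbind(x, confounds)
  }
  cbind(x, intercept = 1)
}

#' Estimate single-trial amplitudes with the least-squares-separate GLM
#'
#' Loops over trials; for each trial, fits an ordinary-least-squares GLM with
#' the [build_lss_design()] design (trial of interest + all other trials +
#' confounds + intercept) to every region's time series simultaneously, and
#' stores the trial-of-interest coefficient. The concatenation over trials is
#' the beta series. The solver is QR-based and rank-revealing: a
#' rank-deficient design is an error naming the collinear columns, never a
#' silent pseudo-inverse.
#'
#' @param timeseries Scans x regions numeric matrix.
#' @param design A [generate_task_design()] design.
#' @param confounds Nuisance regressor table (rows = scans), or `NULL`.
#' @param hrf An [hrf_model()].
#' @return A [beta_series()] with one row per trial.
#' @export
estimate_beta_series <- function(timeseries, design, confounds = NULL,
                                 hrf = hrf_model(tr_s = design$tr_s)) {
  timeseries <- as.matrix(timeseries)
  if (any(!is.finite(timeseries))) {
    stop("timeseries must be finite", call. = FALSE)
  }
  if (nrow(timeseries) != design$n_scans) {
    stop("timeseries has ", nrow(timeseries), " scans but the design expects ",
      design$n_scans,
      call. = FALSE
    )
  }
  n_trials <- n_design_trials(design)
  betas <- matrix(NA_real_, n_trials, ncol(timeseries))
  colnames(betas) <- colnames(timeseries)
  for (t in seq_len(n_trials)) {
    x <- build_lss_design(design, t, confounds, design$n_scans, hrf)
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      bad <- colnames(x)[qx$pivot[seq.int(qx$rank + 1L, ncol(x))]]
      stop(
        "rank-deficient LSS design for trial ", t, "; collinear column(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    coefs <- qr.coef(qx, timeseries)
    betas[t, ] <- coefs["trial_of_interest", ]
  }
  beta_series(betas, design$trials$condition)
}

#' Screen a subject's head motion
#'
#' Computes total displacement as the maximum over scans of the Euclidean
#' norm of the three translation parameters relative to the first (reference)
#' scan; rotations are not included. The subject is excluded when total
#' displacement strictly exceeds `threshold_mm` (the conventional 3 mm
#' cut-off by default).
#'
#' @param motion Scans x 6 matrix: three translations (mm) then three
#'   rotations (rad).
#' @param threshold_mm Exclusion threshold in millimetres.
#' @return `"include"` or `"exclude"`, with the observed total displacement
#'   attached as attribute `total_displacement_mm`.
#' @export
screen_motion <- function(motion, threshold_mm = 3) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("motion must have exactly 6 columns (3 translations, 3 rotations), got ",
      ncol(motion),
      call. = FALSE
    )
  }
  trans <- motion[, 1:3, drop = FALSE]
  rel <- sweep(trans, 2, trans[1L, ])
  disp <- sqrt(rowSums(rel^2))
  total <- max(disp)
  decision <- if (total > threshold_mm) "exclude" else "include"
  attr(decision, "total_displacement_mm") <- total
  decision
}
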