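#' Configuration for the end-to-end analysis pipeline
#'
#' Collects everything [run_pipeline()] needs: cohort and design parameters
#' for the synthetic generator (or paths to precomputed inputs), the
#' analysis condition, classifier sweep and permutation settings, the
#' sparsity sweep, and the top-level seed from which all stage substreams
#' derive.
#'
#' When `betas_dir` and `labels_path` are supplied, per-subject beta-series
#' matrices (one delimited file `<subject_id>.tsv` per subject, trials x
#' regions) and the group labels are read from disk instead of simulated;
#' the events table at `events_path` provides the per-trial conditions.
#'
#' @param output_dir Directory for all pipeline outputs (created if
#'   missing).
#' @param n_per_group,n_rois,n_trials,n_switch Synthetic cohort / design
#'   sizes.
#' @param tr_s,iti_s Design timing (seconds).
#' @param within_r,between_r,group_delta_within,group_delta_between,noise_sd
#'   Passed to [simulation_config()].
#' @param condition Trial condition used for connectivity (default
#'   `"switch"`).
#' @param fisher_z Fisher-z transform connectivity features.
#' @param grid_start,grid_step Feature-count sweep grid.
#' @param n_permutations Label permutations for the significance test.
#' @param sparsities Sparsity sweep for the efficiency analysis.
#' @param negative_weights Negative-correlation handling for graphs.
#' @param simulate_bold Simulate BOLD time series from the generated
#'   amplitudes and re-estimate them with the least-squares-separate GLM
#'   (exercises the estimation stage; slower).
#' @param motion_threshold_mm Head-motion exclusion threshold.
#' @param events_path,betas_dir,labels_path Optional precomputed inputs.
#' @param seed Top-level integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("switchconn_run_"),
                            n_per_group = 46, n_rois = 222, n_trials = 96,
                            n_switch = 24, tr_s = 2, iti_s = 6,
                            within_r = 0.4, between_r = 0.1,
                            group_delta_within = -0.1,
                            group_delta_between = -0.05,
                            noise_sd = 1, condition = "switch",
                            fisher_z = FALSE,
                            grid_start = 20, grid_step = 20,
                            n_permutations = 1000,
                            sparsities = seq(0.05, 0.50, by = 0.05),
                            negative_weights = "zero",
                            simulate_bold = FALSE,
                            motion_threshold_mm = 3,
                            events_path = NULL, betas_dir = NULL,
                            labels_path = NULL, seed = 1L) {
  for (p in c(events_path, betas_dir, labels_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(
    list(
      output_dir = output_dir,
      n_per_group = n_per_group, n_rois = n_rois, n_trials = n_trials,
      n_switch = n_switch, tr_s = tr_s, iti_s = iti_s,
      within_r = within_r, between_r = between_r,
      group_delta_within = group_delta_within,
      group_delta_between = group_delta_between,
      noise_sd = noise_sd, condition = condition, fisher_z = fisher_z,
      grid_start = grid_start, grid_step = grid_step,
      n_permutations = n_permutations,
      sparsities = sparsities, negative_weights = negative_weights,
      simulate_bold = simulate_bold,
      motion_threshold_mm = motion_threshold_mm,
      events_path = events_path, betas_dir = betas_dir,
      labels_path = labels_path,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[switchconn] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: task-design generation (or events loading), cohort
#' simulation (or beta-series loading), optional BOLD simulation and
#' least-squares-separate re-estimation, head-motion screening, behavioural
#' group comparison, per-subject beta-series connectivity for the analysis
#' condition, connectome-based LOOCV classification with the feature-count
#' sweep and a label-permutation test, and the weighted-network efficiency
#' analysis with group comparisons of the AUC summaries. All machine-
#' readable intermediates are written under `config$output_dir`, and the
#' whole run is deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `run_report` (also serialised to
#'   `report.json` / `report.txt` in the output directory).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # --- design ---------------------------------------------------------
  if (!is.null(config$events_path)) {
    design <- read_events(config$events_path, tr_s = config$tr_s)
    pipeline_log(verbose, "loaded events: ", n_design_trials(design), " trials")
  } else {
    design <- generate_task_design(
      config$n_trials, config$n_switch, config$tr_s, config$iti_s,
      seed = config$seed
    )
    pipeline_log(
      verbose, "generated design: ", config$n_trials, " trials (",
      config$n_switch, " switch)"
    )
  }
  write_events(design, file.path(out, "events.tsv"))

  # --- cohort ---------------------------------------------------------
  behavior <- NULL
  if (!is.null(config$betas_dir)) {
    labels_df <- read_labels(config$labels_path)
    subjects <- lapply(seq_len(nrow(labels_df)), function(i) {
      sid <- labels_df$subject_id[i]
      vals <- read_matrix(file.path(config$betas_dir, paste0(sid, ".tsv")))
      list(
        subject_id = sid, group = labels_df$group[i],
        beta_series = beta_series(vals, design$trials$condition),
        motion = NULL, behavior = NULL
      )
    })
    names(subjects) <- labels_df$subject_id
    pipeline_log(verbose, "loaded ", length(subjects), " beta-series matrices")
  } else {
    sim_cfg <- simulation_config(
      n_per_group = config$n_per_group, n_rois = config$n_rois,
      n_trials = n_design_trials(design),
      within_r = config$within_r, between_r = config$between_r,
      group_delta_within = config$group_delta_within,
      group_delta_between = config$group_delta_between,
      noise_sd = config$noise_sd, seed = config$seed
    )
    subjects <- generate_group_beta_series(sim_cfg, design)
    pipeline_log(
      verbose, "simulated cohort: ", length(subjects), " subjects x ",
      config$n_rois, " regions"
    )
  }
  groups <- vapply(subjects, `[[`, "", "group")
  labels_df <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = groups, stringsAsFactors = FALSE
  )
  write_labels(labels_df, file.path(out, "labels.tsv"))

  # --- optional BOLD simulation + LSS re-estimation -------------------
  if (config$simulate_bold) {
    pipeline_log(verbose, "simulating BOLD and re-estimating betas (LSS)")
    for (i in seq_along(subjects)) {
      bold <- generate_bold_timeseries(
        design, subjects[[i]]$beta_series$values,
        noise_sd = config$noise_sd,
        seed = substream_seed(config$seed, "bold", i)
      )
      subjects[[i]]$beta_series <- estimate_beta_series(
        bold$timeseries, design, bold$confounds
      )
    }
  }

  # --- motion screening -----------------------------------------------
  screened <- vapply(subjects, function(s) {
    if (is.null(s$motion)) "include" else as.character(screen_motion(s$motion, config$motion_threshold_mm))
  }, "")
  n_excluded <- sum(screened == "exclude")
  pipeline_log(verbose, "motion screening: ", n_excluded, " subject(s) excluded")
  subjects <- subjects[screened == "include"]
  groups <- groups[screened == "include"]

  # --- behaviour -------------------------------------------------------
  have_behavior <- !is.null(subjects[[1L]]$behavior)
  if (have_behavior) {
    rt <- vapply(subjects, function(s) s$behavior$mean_rt_ms, 0)
    acc <- vapply(subjects, function(s) s$behavior$accuracy_fraction, 0)
    behavior <- list(
      response_time = compare_groups(rt[groups == "patient"], rt[groups == "control"]),
      accuracy = compare_groups(acc[groups == "patient"], acc[groups == "control"])
    )
  }

  # --- connectivity ----------------------------------------------------
  pipeline_log(verbose, "computing beta-series connectivity ('", config$condition, "' trials)")
  matrices <- lapply(subjects, function(s) {
    beta_series_correlation(s$beta_series, config$condition, fisher_z = config$fisher_z)
  })
  n_feat <- nrow(upper_tri_pairs(length(matrices[[1L]]$roi_labels)))
  feats <- t(vapply(
    matrices,
    function(m) vectorize_upper_triangle(m)$values,
    numeric(n_feat)
  ))
  rownames(feats) <- labels_df$subject_id[screened == "include"]

  # --- classification --------------------------------------------------
  pipeline_log(
    verbose, "LOOCV sweep over ", length(feature_count_grid(
      ncol(feats), config$grid_start, config$grid_step
    )), " feature counts"
  )
  cls <- sweep_feature_counts(
    feats, groups,
    grid_start = config$grid_start,
    grid_step = config$grid_step
  )
  perm <- permutation_test(
    feats, groups, cls$selected_feature_count,
    n_permutations = config$n_permutations,
    seed = substream_seed(config$seed, "perm_stage"),
    observed_accuracy = cls$accuracy
  )
  utils::write.table(
    cls$accuracy_by_feature_count, file.path(out, "sweep_accuracy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    cls$records, file.path(out, "subject_predictions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    cls$roc_points, file.path(out, "roc_points.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(
    c(provenance_header("null_accuracies", config$seed), fmt_num(perm$null_accuracies)),
    file.path(out, "null_accuracies.tsv")
  )

  # --- network efficiency ----------------------------------------------
  pipeline_log(verbose, "efficiency sweep over ", length(config$sparsities), " sparsities")
  curves <- lapply(matrices, function(m) {
    suppressWarnings(efficiency_curve(m, config$sparsities, config$negative_weights))
  })
  eg_auc <- vapply(curves, `[[`, 0, "eg_auc")
  eloc_auc <- vapply(curves, `[[`, 0, "eloc_auc")
  eff_cmp <- list(
    global_efficiency = compare_groups(
      eg_auc[groups == "patient"], eg_auc[groups == "control"]
    ),
    local_efficiency = compare_groups(
      eloc_auc[groups == "patient"], eloc_auc[groups == "control"]
    )
  )
  auc_subject_ids <- labels_df$subject_id[screened == "include"]
  curve_rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(
      subject_id = auc_subject_ids[i],
      group = unname(groups[i]),
      sparsity = curves[[i]]$sparsities,
      global_efficiency = curves[[i]]$eg_values,
      local_efficiency = curves[[i]]$eloc_values,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(curve_rows, file.path(out, "efficiency_curves.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  auc_rows <- data.frame(
    subject_id = auc_subject_ids,
    group = unname(groups), eg_auc = unname(eg_auc), eloc_auc = unname(eloc_auc),
    stringsAsFactors = FALSE
  )
  utils::write.table(auc_rows, file.path(out, "efficiency_auc.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  # --- report -----------------------------------------------------------
  cmp_list <- function(cmp) {
    list(
      t = cmp$t_statistic, df = cmp$degrees_of_freedom, p = cmp$p_value,
      mean_patient = cmp$mean_a, mean_control = cmp$mean_b
    )
  }
  report <- structure(
    list(
      package_version = as.character(utils::packageVersion("switchconn")),
      seed = config$seed,
      config = unclass(config),
      n_subjects = length(subjects),
      n_excluded_motion = n_excluded,
      behavior = if (have_behavior) lapply(behavior, cmp_list),
      classification = list(
        selected_feature_count = cls$selected_feature_count,
        accuracy = cls$accuracy,
        sensitivity = cls$sensitivity,
        specificity = cls$specificity,
        auc = cls$auc,
        permutation_p = perm$p_value,
        n_permutations = perm$n_permutations
      ),
      efficiency = lapply(eff_cmp, cmp_list)
    ),
    class = "run_report"
  )
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out, "report.txt"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== switchconn run report ==\n")
  cat(sprintf(
    "subjects: %d (%d excluded for motion); seed %d\n",
    x$n_subjects, x$n_excluded_motion, x$seed
  ))
  if (!is.null(x$behavior)) {
    cat(sprintf(
      "behaviour: RT t(%d) = %.2f (p = %.3g); accuracy t(%d) = %.2f (p = %.3g)\n",
      x$behavior$response_time$df, x$behavior$response_time$t,
      x$behavior$response_time$p,
      x$behavior$accuracy$df, x$behavior$accuracy$t, x$behavior$accuracy$p
    ))
  }
  cl <- x$classification
  cat(sprintf(
    "classification: %d features; accuracy %.2f%% (sens %.2f%%, spec %.2f%%), AUC %.4f, permutation p = %.4g\n",
    cl$selected_feature_count, cl$accuracy, cl$sensitivity, cl$specificity,
    cl$auc, cl$permutation_p
  ))
  eff <- x$efficiency
  cat(sprintf(
    "efficiency AUC (patient vs control): Eg t(%d) = %.2f (p = %.3g); Eloc t(%d) = %.2f (p = %.3g)\n",
    eff$global_efficiency$df, eff$global_efficiency$t, eff$global_efficiency$p,
    eff$local_efficiency$df, eff$local_efficiency$t, eff$local_efficiency$p
  ))
  invisible(x)
}
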