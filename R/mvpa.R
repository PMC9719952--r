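#' F-score feature ranking
#'
#' Scores every feature by the ratio of its between-group mean separation to
#' its within-group variance:
#' \deqn{F(i) = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} - \bar x_i)^2}
#'   {s^2_{+,i} + s^2_{-,i}}}
#' where \eqn{\bar x_i} is the grand mean of feature i, \eqn{\bar x_i^{(\pm)}}
#' the class means, and \eqn{s^2_{\pm,i}} the within-class sample variances
#' (n - 1 denominators). A higher score marks a more discriminative feature.
#'
#' Degenerate features are handled deterministically: zero denominator with a
#' positive numerator scores `Inf` (two constant, different classes are
#' perfectly discriminative and rank first); zero numerator and denominator
#' scores 0. Ranking is by descending score with ties broken by ascending
#' feature index, so it is deterministic and seed-free.
#'
#' @param features Subjects x features numeric matrix.
#' @param labels Class label per subject (exactly two classes, at least two
#'   subjects each).
#' @param positive Label of the positive class (default `"patient"`).
#' @return An object of class `f_score_table`: list with `scores` and
#'   `ranking` (a permutation of feature indices, most discriminative
#'   first).
#' @export
#' @examples
#' x <- rbind(c(2), c(4), c(0), c(2))
#' f_score(x, c("patient", "patient", "control", "control"))$scores # 0.5
f_score <- function(features, labels, positive = "patient") {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  if (!positive %in% classes) {
    stop("positive class '", positive, "' not present in labels", call. = FALSE)
  }
  pos <- labels == positive
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("each class needs at least 2 subjects to compute F-scores", call. = FALSE)
  }
  m_all <- colMeans(features)
  xp <- features[pos, , drop = FALSE]
  xn <- features[!pos, , drop = FALSE]
  num <- (colMeans(xp) - m_all)^2 + (colMeans(xn) - m_all)^2
  den <- col_vars(xp) + col_vars(xn)
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  structure(
    list(
      scores = unname(scores),
      ranking = order(-scores, seq_along(scores)),
      positive = positive
    ),
    class = "f_score_table"
  )
}

# Shared LOOCV engine. For each held-out subject the F-score ranking is
# computed on the training fold only (via class-wise running sums, so a fold
# update is O(features) instead of a full-matrix pass), then a linear
# max-margin classifier (hinge loss, cost C) is trained on the top-k
# features for every k in `ks` and applied to the held-out subject.
# Returns per-subject predictions and signed decision scores (positive
# scores favour the positive class) for every k.
loocv_engine <- function(features, labels, ks, positive = "patient",
                         standardize = TRUE, cost = 1) {
  x <- as.matrix(features)
  n <- nrow(x)
  p <- ncol(x)
  labels <- as.character(labels)
  if (length(labels) != n) stop("need one label per subject", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) != 2L || !positive %in% classes) {
    stop("labels must contain exactly two classes including the positive class",
      call. = FALSE
    )
  }
  negative <- setdiff(classes, positive)
  ks <- as.integer(ks)
  if (length(ks) == 0L || any(ks < 1L) || any(ks > p)) {
    stop("feature counts must lie in [1, ", p, "]", call. = FALSE)
  }
  pos <- labels == positive
  s_pos <- colSums(x[pos, , drop = FALSE])
  s2_pos <- colSums(x[pos, , drop = FALSE]^2)
  s_neg <- colSums(x[!pos, , drop = FALSE])
  s2_neg <- colSums(x[!pos, , drop = FALSE]^2)
  n_pos <- sum(pos)
  n_neg <- n - n_pos
  predicted <- matrix(NA_character_, n, length(ks))
  scores <- matrix(NA_real_, n, length(ks))
  for (i in seq_len(n)) {
    xi <- x[i, ]
    if (pos[i]) {
      np <- n_pos - 1L; sp <- s_pos - xi; sp2 <- s2_pos - xi^2
      nn <- n_neg; sn <- s_neg; sn2 <- s2_neg
    } else {
      np <- n_pos; sp <- s_pos; sp2 <- s2_pos
      nn <- n_neg - 1L; sn <- s_neg - xi; sn2 <- s2_neg - xi^2
    }
    if (np < 2L || nn < 2L) {
      stop("training fold for subject ", i, " has a class with fewer than 2 members",
        call. = FALSE
      )
    }
    m_pos <- sp / np
    m_neg <- sn / nn
    m_all <- (sp + sn) / (np + nn)
    v_pos <- pmax((sp2 - np * m_pos^2) / (np - 1L), 0)
    v_neg <- pmax((sn2 - nn * m_neg^2) / (nn - 1L), 0)
    num <- (m_pos - m_all)^2 + (m_neg - m_all)^2
    den <- v_pos + v_neg
    sc <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
    ranking <- order(-sc, seq_along(sc))
    tr <- setdiff(seq_len(n), i)
    y_tr <- factor(labels[tr], levels = c(positive, negative))
    for (j in seq_along(ks)) {
      sel <- ranking[seq_len(ks[j])]
      xtr <- x[tr, sel, drop = FALSE]
      xte <- x[i, sel, drop = FALSE]
      if (standardize) {
        mu <- colMeans(xtr)
        sdev <- sqrt(col_vars(xtr))
        sdev[!is.finite(sdev) | sdev == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mu), 2, sdev, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sdev, "/")
      }
      fit <- e1071::svm(xtr, y_tr, kernel = "linear", cost = cost, scale = FALSE)
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      score <- drop(dv)[1L]
      if (!startsWith(colnames(dv)[1L], paste0(positive, "/"))) score <- -score
      predicted[i, j] <- as.character(pr[1L])
      scores[i, j] <- score
    }
  }
  list(
    predicted = predicted, scores = scores, ks = ks,
    labels = labels, positive = positive, negative = negative
  )
}

engine_records <- function(eng, j) {
  data.frame(
    subject = seq_along(eng$labels),
    true_label = eng$labels,
    predicted_label = eng$predicted[, j],
    decision_score = eng$scores[, j],
    stringsAsFactors = FALSE
  )
}

#' Leave-one-out cross-validated classification at a fixed feature count
#'
#' For each subject in turn: rank all features by [f_score()] on the
#' remaining (training) subjects only, keep the top `k`, optionally
#' standardise features to the training fold's mean/SD, train a linear
#' max-margin classifier (hinge loss, regularisation constant `cost`), and
#' predict the held-out subject, recording its signed decision score
#' (positive = evidence for the positive class). Feature selection and
#' standardisation happen strictly inside each training fold, so no
#' information from the held-out subject leaks into the model.
#'
#' @param features Subjects x features matrix.
#' @param labels Two-class label per subject.
#' @param k Number of top-ranked features to keep.
#' @param positive Positive class label (default `"patient"`).
#' @param standardize Standardise selected features using training-fold
#'   mean/SD before fitting (recommended for correlation features).
#' @param cost Regularisation constant C of the margin classifier.
#' @return Data frame with one row per subject: `subject`, `true_label`,
#'   `predicted_label`, `decision_score`.
#' @export
loocv_classify <- function(features, labels, k, positive = "patient",
                           standardize = TRUE, cost = 1) {
  eng <- loocv_engine(features, labels, k, positive, standardize, cost)
  engine_records(eng, 1L)
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity and specificity (as percentages) from per-subject
#' LOOCV records, with patients as the positive class:
#' accuracy = (TP + TN) / (TP + TN + FP + FN), sensitivity = TP / (TP + FN)
#' (patients correctly classified), specificity = TN / (TN + FP) (controls
#' correctly classified).
#'
#' @param records Data frame with `true_label` and `predicted_label` columns
#'   (as returned by [loocv_classify()]).
#' @param positive Positive class label.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
classification_metrics <- function(records, positive = "patient") {
  truth <- records$true_label
  pred <- records$predicted_label
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  is_pos <- truth == positive
  if (!any(is_pos)) {
    stop("no positive-class subjects: sensitivity is undefined", call. = FALSE)
  }
  if (all(is_pos)) {
    stop("no negative-class subjects: specificity is undefined", call. = FALSE)
  }
  tp <- sum(is_pos & pred == positive)
  fn <- sum(is_pos & pred != positive)
  tn <- sum(!is_pos & pred != positive)
  fp <- sum(!is_pos & pred == positive)
  list(
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps the classification threshold over the observed decision scores to
#' trace the receiver operating characteristic, and computes the area under
#' the curve as the Mann-Whitney probability that a randomly chosen
#' positive-class subject scores higher than a randomly chosen
#' negative-class subject, with ties counting one half.
#'
#' @param records Data frame with `true_label` and `decision_score` columns.
#' @param positive Positive class label.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`. Constant scores give AUC 0.5 with a warning.
#' @export
roc_curve_auc <- function(records, positive = "patient") {
  scores <- records$decision_score
  truth <- records$true_label == positive
  if (!any(truth) || all(truth)) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("decision scores must be finite", call. = FALSE)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(th) sum(scores[!truth] >= th) / n_neg, 0),
    tpr = vapply(thresholds, function(th) sum(scores[truth] >= th) / n_pos, 0)
  )
  if (length(unique(scores)) == 1L) {
    warning("all decision scores are identical; AUC set to 0.5", call. = FALSE)
    return(list(points = points, auc = 0.5))
  }
  r <- rank(scores) # midranks handle ties as 1/2 wins
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(points = points, auc = auc)
}

#' Feature-count grid for the LOOCV sweep
#'
#' The grid of candidate feature counts: `grid_start`, `grid_start +
#' grid_step`, ... up to (but excluding) the total feature count. For the
#' 24,531 pairwise features of a 222-region network with start 20 and step
#' 20 the grid ends at 24,520, and grid position 207 is 4,140 features.
#'
#' @param n_features Total number of features.
#' @param grid_start First feature count.
#' @param grid_step Grid increment.
#' @return Integer vector of feature counts.
#' @export
feature_count_grid <- function(n_features, grid_start = 20, grid_step = 20) {
  n_features <- as.integer(n_features)
  if (grid_start < 1 || grid_start >= n_features) {
    stop("empty feature-count grid: grid_start must lie in [1, n_features)",
      call. = FALSE
    )
  }
  seq.int(as.integer(grid_start), n_features - 1L, by = as.integer(grid_step))
}

#' LOOCV classification with a feature-count sweep
#'
#' Runs [loocv_classify()] at every feature count of the
#' [feature_count_grid()], computes the LOOCV accuracy curve, and selects
#' the smallest feature count attaining the maximum accuracy. Per-fold
#' feature rankings are computed once and shared across the grid, so the
#' sweep costs one ranking plus one classifier fit per (fold, grid value).
#'
#' @inheritParams loocv_classify
#' @param grid_start,grid_step Feature-count grid parameters.
#' @return An object of class `classification_result`: per-subject `records`
#'   at the selected feature count, `selected_feature_count`, summary
#'   `accuracy`, `sensitivity`, `specificity` (percent), `auc`, and the full
#'   sweep curve `accuracy_by_feature_count` (data frame `n_features`,
#'   `accuracy`).
#' @export
sweep_feature_counts <- function(features, labels, grid_start = 20,
                                 grid_step = 20, positive = "patient",
                                 standardize = TRUE, cost = 1) {
  ks <- feature_count_grid(ncol(as.matrix(features)), grid_start, grid_step)
  eng <- loocv_engine(features, labels, ks, positive, standardize, cost)
  acc <- vapply(seq_along(ks), function(j) {
    100 * mean(eng$predicted[, j] == eng$labels)
  }, 0)
  best <- which(acc == max(acc))[1L] # smallest k attaining the maximum
  records <- engine_records(eng, best)
  metrics <- classification_metrics(records, positive)
  roc <- roc_curve_auc(records, positive)
  structure(
    list(
      records = records,
      selected_feature_count = ks[best],
      accuracy = metrics$accuracy,
      sensitivity = metrics$sensitivity,
      specificity = metrics$specificity,
      auc = roc$auc,
      roc_points = roc$points,
      accuracy_by_feature_count = data.frame(n_features = ks, accuracy = acc)
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Connectome-based LOOCV classification\n")
  cat(sprintf(
    "  selected features: %d\n  accuracy: %.2f%%  sensitivity: %.2f%%  specificity: %.2f%%  AUC: %.4f\n",
    x$selected_feature_count, x$accuracy, x$sensitivity, x$specificity, x$auc
  ))
  invisible(x)
}

#' Label-permutation significance test for LOOCV accuracy
#'
#' Repeatedly shuffles the group labels, reruns the full LOOCV
#' classification (feature ranking inside each training fold) at the fixed
#' selected feature count, and records the null accuracy. The p-value is the
#' number of permutations whose accuracy strictly exceeds the observed
#' accuracy divided by the number of permutations — the plain empirical
#' exceedance fraction with no +1 correction, so an observed accuracy below
#' every null accuracy gives p = 1 and one above every null gives p = 0.
#'
#' Rerunning only the selected feature count (rather than the full sweep)
#' per permutation keeps the null computationally tractable;
#' `sweep_per_permutation = TRUE` reruns the entire feature-count sweep in
#' each permutation instead.
#'
#' @inheritParams loocv_classify
#' @param k_selected Feature count at which the null is evaluated.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed for the permutation stream.
#' @param observed_accuracy Observed LOOCV accuracy (percent); computed at
#'   `k_selected` when omitted.
#' @param sweep_per_permutation Rerun the full feature-count sweep per
#'   permutation (expensive).
#' @param grid_start,grid_step Sweep grid when `sweep_per_permutation`.
#' @return An object of class `permutation_result`: `observed_accuracy`,
#'   `null_accuracies`, `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(features, labels, k_selected, n_permutations = 1000,
                             seed = 1L, observed_accuracy = NULL,
                             positive = "patient", standardize = TRUE, cost = 1,
                             sweep_per_permutation = FALSE,
                             grid_start = 20, grid_step = 20) {
  if (n_permutations < 1L) stop("n_permutations must be at least 1", call. = FALSE)
  labels <- as.character(labels)
  if (is.null(observed_accuracy)) {
    obs <- loocv_classify(features, labels, k_selected, positive, standardize, cost)
    observed_accuracy <- classification_metrics(obs, positive)$accuracy
  }
  null_acc <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- withr::with_seed(
      substream_seed(seed, "permutation", b),
      sample(labels)
    )
    acc_b <- if (sweep_per_permutation) {
      sweep_feature_counts(features, perm, grid_start, grid_step, positive,
        standardize, cost
      )$accuracy
    } else {
      rec <- loocv_classify(features, perm, k_selected, positive, standardize, cost)
      100 * mean(rec$predicted_label == rec$true_label)
    }
    null_acc[b] <- acc_b
  }
  structure(
    list(
      observed_accuracy = observed_accuracy,
      null_accuracies = null_acc,
      p_value = sum(null_acc > observed_accuracy) / n_permutations,
      n_permutations = n_permutations,
      seed = as.integer(seed)
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed accuracy %.2f%%, p = %.4g (%d permutations)\n",
    x$observed_accuracy, x$p_value, x$n_permutations
  ))
  invisible(x)
}
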