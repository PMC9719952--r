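#' Beta-series correlation connectivity matrix
#'
#' Computes, for the trials of the requested condition, the Pearson
#' correlation of trial-by-trial response variability between every pair of
#' regions. The result is the subject's condition-specific functional
#' connectivity (FC) matrix: symmetric with unit diagonal. Correlation
#' coefficients are used directly as connection weights; an optional Fisher
#' z-transform (`atanh`) of the off-diagonal entries is available but off by
#' default.
#'
#' @param betas A [beta_series()].
#' @param condition Which trial condition to restrict to (default
#'   `"switch"`); `NULL` pools all trials.
#' @param fisher_z Apply the Fisher z-transform to off-diagonal entries.
#' @return An object of class `connectivity_matrix`: list with `values`
#'   (regions x regions matrix), `roi_labels`, and `condition`.
#' @export
#' @examples
#' b <- beta_series(matrix(rnorm(40), 10, dimnames = list(NULL, paste0("R", 1:4))),
#'   rep(c("switch", "repeat"), 5)
#' )
#' fc <- beta_series_correlation(b, "switch")
#' fc$values[1, 1]
beta_series_correlation <- function(betas, condition = "switch", fisher_z = FALSE) {
  stopifnot(inherits(betas, "beta_series"))
  sel <- if (is.null(condition)) {
    rep(TRUE, nrow(betas$values))
  } else {
    betas$condition_labels == condition
  }
  if (sum(sel) < 3L) {
    stop(
      "need at least 3 trials in condition '", condition %||% "all",
      "' to estimate correlations (got ", sum(sel), ")",
      call. = FALSE
    )
  }
  x <- betas$values[sel, , drop = FALSE]
  labels <- colnames(x) %||% sprintf("ROI%03d", seq_len(ncol(x)))
  v <- col_vars(x)
  if (any(v <= 0)) {
    stop(
      "zero-variance beta series for region(s): ",
      paste(labels[v <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  r <- stats::cor(x)
  if (fisher_z) {
    d <- diag(nrow(r))
    r <- atanh(pmin(pmax(r, -1), 1)) * (1 - d)
  }
  diag(r) <- 1
  dimnames(r) <- list(labels, labels)
  structure(
    list(values = r, roi_labels = labels, condition = condition %||% "all"),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(
    "Connectivity matrix: ", length(x$roi_labels), " x ", length(x$roi_labels),
    " regions, condition '", x$condition, "'\n",
    sep = ""
  )
  invisible(x)
}

conn_values <- function(x, what = "matrix") {
  if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
}

#' Vectorise the upper triangle of a symmetric connectivity matrix
#'
#' Flattens a symmetric regions x regions matrix into the fixed-order
#' feature vector used for classification: positions follow row-major
#' upper-triangle order (1,2), (1,3), ..., (1,n), (2,3), ..., giving
#' n(n-1)/2 features (24,531 for a 222-region network). The position-to-pair
#' mapping is returned so features can be mapped back to region pairs.
#'
#' @param matrix A `connectivity_matrix` or plain symmetric matrix.
#' @param tol Maximum tolerated asymmetry.
#' @return An object of class `feature_vector`: list with `values`
#'   (length n(n-1)/2) and `index_map` (data frame `feature`, `i`, `j`).
#' @seealso [devectorize_upper_triangle()]
#' @export
vectorize_upper_triangle <- function(matrix, tol = 1e-10) {
  m <- conn_values(matrix)
  check_symmetric(m, tol, "connectivity matrix")
  n <- nrow(m)
  pairs <- upper_tri_pairs(n)
  labels <- rownames(m) %||% sprintf("ROI%03d", seq_len(n))
  structure(
    list(
      values = m[cbind(pairs$i, pairs$j)],
      index_map = data.frame(
        feature = seq_len(nrow(pairs)),
        i = pairs$i, j = pairs$j,
        roi_i = labels[pairs$i], roi_j = labels[pairs$j],
        stringsAsFactors = FALSE
      )
    ),
    class = "feature_vector"
  )
}

#' Rebuild a symmetric matrix from an upper-triangle feature vector
#'
#' Inverse of [vectorize_upper_triangle()]: restores the off-diagonal
#' entries exactly and sets the diagonal to `diag_value`.
#'
#' @param fv A `feature_vector`.
#' @param diag_value Value for the diagonal (1 for correlation matrices).
#' @return A symmetric numeric matrix.
#' @export
devectorize_upper_triangle <- function(fv, diag_value = 1) {
  stopifnot(inherits(fv, "feature_vector"))
  n <- max(fv$index_map$j)
  m <- matrix(0, n, n)
  m[cbind(fv$index_map$i, fv$index_map$j)] <- fv$values
  m <- m + t(m)
  diag(m) <- diag_value
  labels <- unique(c(fv$index_map$roi_i, fv$index_map$roi_j))
  if (length(labels) == n) dimnames(m) <- list(labels, labels)
  m
}

#' Group-mean connectivity matrices and their difference
#'
#' Entrywise means of each group's connectivity matrices and the
#' control-minus-patient difference matrix, e.g. for displaying the group FC
#' patterns and where they diverge.
#'
#' @param patients,controls Lists of `connectivity_matrix` objects sharing
#'   the same region labels.
#' @return List with `mean_patient`, `mean_control` and `difference`
#'   (control minus patient) matrices.
#' @export
group_mean_and_difference <- function(patients, controls) {
  all_mats <- c(patients, controls)
  labels <- all_mats[[1]]$roi_labels
  for (m in all_mats) {
    if (!identical(m$roi_labels, labels)) {
      stop("all connectivity matrices must share the same region labels",
        call. = FALSE
      )
    }
  }
  avg <- function(ms) Reduce(`+`, lapply(ms, conn_values)) / length(ms)
  mean_patient <- avg(patients)
  mean_control <- avg(controls)
  list(
    mean_patient = mean_patient,
    mean_control = mean_control,
    difference = mean_control - mean_patient
  )
}
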