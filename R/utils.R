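# Internal helpers shared across modules.

# Deterministic substream seed derivation: all randomness in the package
# flows from one top-level seed through named per-stage substreams, so
# stages can be re-run independently and still be reproducible.
# The modulus keeps derived seeds inside the 32-bit integer range.
substream_seed <- function(seed, stage, index = 0L) {
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars))
  val <- (abs(as.numeric(seed)) * 48271 + h * 7919 + as.numeric(index) * 104729) %%
    2147483629
  as.integer(val)
}

# round() in R rounds half to even; sparsity thresholding wants
# round-half-away-from-zero so edge counts match the usual convention.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Row-major upper-triangle (i < j) pair index used for feature vectors and
# edge lists: (1,2), (1,3), ..., (1,n), (2,3), ...
upper_tri_pairs <- function(n) {
  if (n < 2L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) seq.int(k + 1L, n)))
  data.frame(i = i, j = j)
}

# Sample (without the 1:x surprise of sample()) from an explicit vector.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

col_vars <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  pmax((colSums(x^2) - n * m^2) / (n - 1), 0)
}

trapezoid_auc <- function(x, y) {
  if (length(x) < 2L) {
    return(0)
  }
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric (tolerance ", tol, ")", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
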