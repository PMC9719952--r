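#' Canonical double-gamma haemodynamic response model
#'
#' Parameterises the canonical haemodynamic response function (HRF) as the
#' difference of two gamma densities: a positive lobe peaking a few seconds
#' after stimulus onset and a delayed, smaller undershoot. The defaults are
#' the conventional canonical parameterisation (peak delay 6 s, undershoot
#' delay 16 s, unit dispersions, peak:undershoot ratio 6, 32 s support).
#'
#' @param tr_s Repetition time in seconds (sampling interval of the kernel).
#' @param duration_s Length of the kernel support in seconds.
#' @param peak_delay_s Delay of the response peak, seconds.
#' @param undershoot_delay_s Delay of the undershoot, seconds.
#' @param peak_dispersion,undershoot_dispersion Dispersions (gamma scale
#'   parameters) of the two lobes.
#' @param peak_undershoot_ratio Ratio of peak amplitude to undershoot
#'   amplitude.
#'
#' @return An object of class `hrf_model`.
#' @seealso [sample_canonical_hrf()]
#' @export
#' @examples
#' hrf <- hrf_model(tr_s = 2)
#' kernel <- sample_canonical_hrf(hrf)
#' length(kernel) # floor(32 / 2) + 1 = 17 samples
hrf_model <- function(tr_s = 2, duration_s = 32, peak_delay_s = 6,
                      undershoot_delay_s = 16, peak_dispersion = 1,
                      undershoot_dispersion = 1, peak_undershoot_ratio = 6) {
  if (tr_s <= 0) stop("tr_s must be positive", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  structure(
    list(
      tr_s = tr_s,
      duration_s = duration_s,
      peak_delay_s = peak_delay_s,
      undershoot_delay_s = undershoot_delay_s,
      peak_dispersion = peak_dispersion,
      undershoot_dispersion = undershoot_dispersion,
      peak_undershoot_ratio = peak_undershoot_ratio
    ),
    class = "hrf_model"
  )
}

# Unnormalised double-gamma response evaluated at arbitrary times (seconds).
hrf_values <- function(t, model) {
  peak <- stats::dgamma(t,
    shape = model$peak_delay_s / model$peak_dispersion,
    scale = model$peak_dispersion
  )
  under <- stats::dgamma(t,
    shape = model$undershoot_delay_s / model$undershoot_dispersion,
    scale = model$undershoot_dispersion
  )
  peak - under / model$peak_undershoot_ratio
}

#' Sample the canonical HRF kernel on the scan grid
#'
#' Evaluates the double-gamma response of an [hrf_model()] at
#' `0, tr_s, 2 tr_s, ...` over the kernel support and normalises the sampled
#' kernel so its maximum is exactly 1. The kernel has
#' `floor(duration_s / tr_s) + 1` samples.
#'
#' @param model An [hrf_model()].
#' @return Numeric vector of kernel samples (attribute `times_s` holds the
#'   sampling times).
#' @export
sample_canonical_hrf <- function(model = hrf_model()) {
  times <- seq(0, by = model$tr_s, length.out = floor(model$duration_s / model$tr_s) + 1L)
  k <- hrf_values(times, model)
  k <- k / max(k)
  attr(k, "times_s") <- times
  k
}

# HRF-convolved stick regressor sampled at scan times. Events are placed on
# an oversampled grid (tr_s / oversample resolution) so onsets need not lie
# on the scan grid; the fine kernel is normalised by its own maximum so a
# unit-amplitude isolated event has peak response ~1.
convolve_events <- function(onsets_s, n_scans, tr_s, hrf, oversample = 16L) {
  if (length(onsets_s) == 0L) {
    return(numeric(n_scans))
  }
  dt <- tr_s / oversample
  n_fine <- n_scans * oversample
  if (any(onsets_s < 0) || any(onsets_s >= n_scans * tr_s)) {
    stop("event onsets must lie within [0, n_scans * tr_s)", call. = FALSE)
  }
  sticks <- numeric(n_fine)
  idx <- floor(onsets_s / dt) + 1L
  for (i in idx) sticks[i] <- sticks[i] + 1
  kt <- seq(0, hrf$duration_s, by = dt)
  kernel <- hrf_values(kt, hrf)
  kernel <- kernel / max(kernel)
  conv <- stats::convolve(c(sticks, numeric(length(kernel))), rev(kernel), type = "open")
  fine <- conv[seq_len(n_fine)]
  fine[seq(1L, n_fine, by = oversample)]
}
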