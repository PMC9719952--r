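#' Generate a cued task-switching trial design
#'
#' Builds a pseudorandomised cued task-switching run in which participants
#' alternate between a shape task and a color task. A trial is a *switch*
#' trial when its cued task differs from that of the immediately preceding
#' trial and a *repeat* trial otherwise; the first trial has no predecessor
#' and is labelled repeat, so the requested switch/repeat counts partition
#' all trials exactly. The default design is a 96-trial run with 24 switch
#' and 72 repeat trials.
#'
#' Switch positions are drawn uniformly at random among trials 2..n, the
#' task sequence is derived by flipping the task at each switch, and each
#' trial's cue form (full word, e.g. "SHAPE", or single letter, e.g. "S") is
#' drawn independently. Trials are placed on a jittered onset grid with mean
#' inter-trial interval `iti_s`.
#'
#' @param n_trials Total number of trials.
#' @param n_switch Number of switch trials; must satisfy
#'   `0 <= n_switch <= n_trials - 1`.
#' @param tr_s Repetition time of the accompanying scan, seconds.
#' @param iti_s Mean inter-trial interval, seconds.
#' @param jitter_s Half-width of the uniform onset jitter, seconds; use 0
#'   for a strictly periodic design. Defaults to `iti_s / 4`.
#' @param seed Integer seed; identical arguments and seed give identical
#'   designs.
#'
#' @return An object of class `trial_design`: a list with a `trials` data
#'   frame (`onset_s`, `task`, `cue`, `condition`), plus `tr_s` and
#'   `n_scans` (run length chosen to cover the last trial's haemodynamic
#'   response).
#' @export
#' @examples
#' design <- generate_task_design(96, 24, seed = 1)
#' table(design$trials$condition)
generate_task_design <- function(n_trials = 96, n_switch = 24, tr_s = 2,
                                 iti_s = 6, jitter_s = iti_s / 4, seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be at least 1", call. = FALSE)
  if (n_switch < 0L || n_switch > n_trials - 1L) {
    stop(
      "n_switch must lie in [0, n_trials - 1]: every trial after the first ",
      "is either a switch or a repeat, and trial 1 is always a repeat",
      call. = FALSE
    )
  }
  if (jitter_s < 0 || jitter_s >= iti_s) {
    stop("jitter_s must lie in [0, iti_s) so onsets stay strictly increasing",
      call. = FALSE
    )
  }
  tasks <- c("shape", "color")
  withr::with_seed(substream_seed(seed, "task_design"), {
    condition <- rep("repeat", n_trials)
    if (n_switch > 0L) {
      condition[resample(seq.int(2L, n_trials), n_switch)] <- "switch"
    }
    task <- character(n_trials)
    task[1L] <- resample(tasks, 1L)
    if (n_trials > 1L) {
      for (t in seq.int(2L, n_trials)) {
        task[t] <- if (condition[t] == "switch") setdiff(tasks, task[t - 1L]) else task[t - 1L]
      }
    }
    cue <- resample(c("full_word", "single_letter"), n_trials, replace = TRUE)
    gaps <- iti_s + stats::runif(n_trials, -jitter_s, jitter_s)
    onset_s <- cumsum(gaps)
  })
  # run long enough to cover the last trial's full haemodynamic response
  n_scans <- as.integer(ceiling((max(onset_s) + 32) / tr_s) + 1L)
  structure(
    list(
      trials = data.frame(
        onset_s = onset_s, task = task, cue = cue, condition = condition,
        stringsAsFactors = FALSE
      ),
      tr_s = tr_s,
      n_scans = n_scans
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat(
    "Cued task-switching design: ", nrow(x$trials), " trials (",
    sum(x$trials$condition == "switch"), " switch / ",
    sum(x$trials$condition == "repeat"), " repeat), TR = ", x$tr_s,
    " s, ", x$n_scans, " scans\n",
    sep = ""
  )
  invisible(x)
}

n_design_trials <- function(design) nrow(design$trials)
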