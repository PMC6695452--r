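#' Specify a high/low-cost (HLC) task variant
#'
#' Describes one of the three task variants used throughout the pipeline:
#' \describe{
#'   \item{`"saccade"`}{four fully reward-predictive cues (R+/R- per cost
#'     condition); interleaved unpredictable reward and air-puff trials.}
#'   \item{`"uncertain"`}{one cue per cost condition, reward delivered on
#'     half of the trials irrespective of the cue, so reward delivery itself
#'     is unpredicted.}
#'   \item{`"exploration"`}{two-alternative choice between an R+ and an R-
#'     cue per cost condition; the association must be learned within the
#'     session.}
#' }
#'
#' The cost manipulation is a long gaze fixation in high-cost (HC) trials
#' versus a short one in low-cost (LC) trials. To equalize success rates, a
#' forced abort is inserted in a fraction of LC trials 100 ms before the
#' reward cue would appear.
#'
#' @param task_kind one of `"saccade"`, `"uncertain"`, `"exploration"`.
#' @param n_trials_per_condition number of completed-trial slots per cost
#'   condition (default 40 for saccade/uncertain, 100 for exploration).
#' @param n_unpredictable_reward,n_unpredictable_airpuff uncued delivery
#'   trials mixed into saccade/uncertain sessions.
#' @param fixation_duration_hc HC fixation-target duration in ms.
#' @param blank_duration_lc LC blank-screen duration in ms (followed by a
#'   500 ms fixation target).
#' @param forced_abort_rate_lc probability that an LC trial is terminated
#'   100 ms before reward cue onset.
#' @param abort_rate_hc probability that an HC trial is aborted by a
#'   fixation break.
#' @param reward_prob_uncertain reward probability in the uncertain task.
#' @param reward_volume_ml water volume metadata (not used numerically).
#' @param iti_s inter-trial interval in seconds. The source experiments do
#'   not report its distribution; it is exposed here as a plain knob.
#' @return a `task_spec` list.
#' @export
task_spec <- function(task_kind = c("saccade", "uncertain", "exploration"),
                      n_trials_per_condition = NULL,
                      n_unpredictable_reward = NULL,
                      n_unpredictable_airpuff = NULL,
                      fixation_duration_hc = NULL,
                      blank_duration_lc = NULL,
                      forced_abort_rate_lc = 0.1,
                      abort_rate_hc = 0.1,
                      reward_prob_uncertain = 0.5,
                      reward_volume_ml = 0.3,
                      iti_s = 1.2) {
  task_kind <- match.arg(task_kind)
  defaults <- switch(task_kind,
    saccade     = list(n = 40L, ur = 20L, ap = 20L, fix = 2000, blank = 1500),
    uncertain   = list(n = 40L, ur = 20L, ap = 20L, fix = 2000, blank = 1500),
    exploration = list(n = 100L, ur = 0L, ap = 0L, fix = 1500, blank = 1000)
  )
  n  <- if (is.null(n_trials_per_condition)) defaults$n else as.integer(n_trials_per_condition)
  ur <- if (is.null(n_unpredictable_reward)) defaults$ur else as.integer(n_unpredictable_reward)
  ap <- if (is.null(n_unpredictable_airpuff)) defaults$ap else as.integer(n_unpredictable_airpuff)
  fix   <- if (is.null(fixation_duration_hc)) defaults$fix else fixation_duration_hc
  blank <- if (is.null(blank_duration_lc)) defaults$blank else blank_duration_lc

  stop_if(is.na(n) || n < 1L, "`n_trials_per_condition` must be a positive count")
  stop_if(ur < 0L || ap < 0L, "unpredictable trial counts must be non-negative")
  check_number(fix, "fixation_duration_hc", lower = 0, strict_lower = TRUE)
  check_number(blank, "blank_duration_lc", lower = 0, strict_lower = TRUE)
  check_probability(forced_abort_rate_lc, "forced_abort_rate_lc")
  check_probability(abort_rate_hc, "abort_rate_hc")
  check_probability(reward_prob_uncertain, "reward_prob_uncertain")
  check_number(iti_s, "iti_s", lower = 0)

  structure(list(
    task_kind = task_kind,
    n_trials_per_condition = n,
    n_unpredictable_reward = ur,
    n_unpredictable_airpuff = ap,
    start_cue_duration = 750,
    cost_cue_duration = 750,
    fixation_duration_hc = fix,
    blank_duration_lc = blank,
    lc_target_duration = 500,
    beep_delay = 750,
    forced_abort_rate_lc = forced_abort_rate_lc,
    abort_rate_hc = abort_rate_hc,
    reward_prob_uncertain = reward_prob_uncertain,
    reward_volume_ml = reward_volume_ml,
    iti_s = iti_s
  ), class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s task: %d trials/condition (+%d unpred. reward, +%d air-puff)\n",
              x$task_kind, x$n_trials_per_condition,
              x$n_unpredictable_reward, x$n_unpredictable_airpuff))
  cat(sprintf("  HC fixation %g ms | LC blank %g ms + %g ms target | forced-abort rate (LC) %.2f\n",
              x$fixation_duration_hc, x$blank_duration_lc,
              x$lc_target_duration, x$forced_abort_rate_lc))
  invisible(x)
}
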