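#' Detect saccade onset by the 5-SD deviation rule
#'
#' The onset is the earliest post-cue sample whose gaze deviation from the
#' mean pre-cue position exceeds `threshold_sd` baseline standard
#' deviations, provided the crossing is sustained for `sustain_samples`
#' consecutive samples (6 ms at 500 Hz by default) to reject single-sample
#' noise. The deviation is the 2-D Euclidean distance from the baseline
#' mean by default, with the combined baseline SD
#' `sqrt(sd_x^2 + sd_y^2)`; a per-channel variant tests each axis against
#' its own SD.
#'
#' @param trace a `gaze_trace` (or any data frame with `time_s`, `x_deg`,
#'   `y_deg`, uniformly sampled).
#' @param cue_time cue onset, seconds on the trace clock.
#' @param baseline_window length (s) of the pre-cue baseline (default
#'   0.2 s immediately before the cue).
#' @param threshold_sd detection threshold in baseline SDs (default 5).
#' @param sustain_samples consecutive supra-threshold samples required.
#' @param search_window how far past the cue to search (s).
#' @param mode `"euclidean"` (2-D deviation) or `"per_channel"`.
#' @return onset time in seconds, or `NA` if no sustained crossing. A
#'   degenerate baseline (zero SD) returns `NA` with a warning so the
#'   caller can decide.
#' @export
detect_saccade_onset <- function(trace, cue_time, baseline_window = 0.2,
                                 threshold_sd = 5, sustain_samples = 3L,
                                 search_window = 0.6,
                                 mode = c("euclidean", "per_channel")) {
  mode <- match.arg(mode)
  stop_if(baseline_window <= 0, "`baseline_window` must be positive")
  tt <- trace$time_s
  # binary-search index ranges (tt is sorted)
  span <- function(lo, hi) {
    i <- findInterval(lo - 1e-9, tt) + 1L
    j <- findInterval(hi, tt)
    if (j < i) integer(0) else i:j
  }
  base_idx <- span(cue_time - baseline_window, cue_time - 1e-9)
  stop_if(length(base_idx) < 2L,
          "baseline window must precede the cue and contain >= 2 samples")
  post_idx <- span(cue_time, cue_time + search_window)
  if (length(post_idx) == 0L) return(NA_real_)

  bx <- trace$x_deg[base_idx]; by <- trace$y_deg[base_idx]
  mx <- mean(bx); my <- mean(by)
  sdx <- sd(bx); sdy <- sd(by)

  if (mode == "euclidean") {
    s <- sqrt(sdx^2 + sdy^2)
    if (s == 0) {
      warning("degenerate baseline: zero gaze variability before the cue")
      return(NA_real_)
    }
    dev <- sqrt((trace$x_deg[post_idx] - mx)^2 + (trace$y_deg[post_idx] - my)^2)
    cross <- dev > threshold_sd * s
  } else {
    if (sdx == 0 && sdy == 0) {
      warning("degenerate baseline: zero gaze variability before the cue")
      return(NA_real_)
    }
    cx <- if (sdx > 0) abs(trace$x_deg[post_idx] - mx) > threshold_sd * sdx else FALSE
    cy <- if (sdy > 0) abs(trace$y_deg[post_idx] - my) > threshold_sd * sdy else FALSE
    cross <- cx | cy
  }

  k <- max(1L, as.integer(sustain_samples))
  if (length(cross) < k) return(NA_real_)
  runs <- as.numeric(stats::filter(as.numeric(cross), rep(1, k), sides = 1))
  hit <- which(runs == k)
  if (length(hit) == 0L) return(NA_real_)
  tt[post_idx[hit[1] - k + 1L]]
}

#' Extract reaction times for one session
#'
#' RT is the interval between cue onset and the detected saccade
#' initiation, per completed trial. Aborted trials (including forced
#' aborts) never enter the table; trials where no onset is detected are
#' dropped with a warning.
#'
#' @param events a `session_events` table.
#' @param trace the session's `gaze_trace`.
#' @param event which cue to align to: `"cost_cue"` or `"reward_cue"`.
#' @param ... passed to [detect_saccade_onset()].
#' @return an `rt_table` data frame: `trial_id`, `cost_condition`,
#'   `reward_condition`, `event`, `rt_ms`.
#' @export
compute_reaction_times <- function(events, trace,
                                   event = c("cost_cue", "reward_cue"), ...) {
  event <- match.arg(event)
  keep <- completed_trials(events)
  cue_col <- paste0("t_", event)
  keep <- keep[!is.na(keep[[cue_col]]), , drop = FALSE]
  rt <- vapply(seq_len(nrow(keep)), function(i) {
    on <- suppressWarnings(
      detect_saccade_onset(trace, keep[[cue_col]][i], ...))
    if (is.na(on)) NA_real_ else (on - keep[[cue_col]][i]) * 1000
  }, numeric(1))
  dropped <- sum(is.na(rt))
  if (dropped > 0L) {
    warning(sprintf("%d trial(s) dropped: no saccade onset detected", dropped))
  }
  out <- data.frame(trial_id = keep$trial_id,
                    cost_condition = keep$cost_condition,
                    reward_condition = keep$reward_condition,
                    event = event, rt_ms = rt,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$rt_ms), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rt_table", "data.frame")
  out
}
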