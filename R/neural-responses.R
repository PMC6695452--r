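#' Subject-specific response windows
#'
#' Loads the per-event analysis windows (ms relative to event onset,
#' half-open `[start, end)`) from the packaged YAML config. Windows differ
#' between the two recorded subjects because they were set from each
#' subject's population-averaged response onset/offset.
#'
#' @param subject subject tag, `"P"` or `"S"`.
#' @param path optional alternative YAML file with the same layout.
#' @return named list of `c(start_ms, end_ms)` windows.
#' @export
response_windows <- function(subject = "P", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "response_windows.yaml",
                        package = "dopacost")
  }
  cfg <- yaml::read_yaml(path)
  stop_if(!subject %in% names(cfg$subjects),
          "unknown subject tag: ", subject)
  lapply(cfg$subjects[[subject]], as.numeric)
}

count_in_window <- function(spike_times, starts, ends) {
  # half-open [start, end): count spikes per aligned window
  findInterval(ends - 1e-12, spike_times) - findInterval(starts - 1e-12, spike_times)
}

#' Spontaneous (baseline) firing rate of a neuron
#'
#' Mean firing rate over the 500 ms preceding start cue onset, averaged
#' across the session's completed trials (per-neuron baseline).
#'
#' @param neuron a `neuron_record`.
#' @param events a `session_events` table.
#' @param window_s baseline window relative to the start cue, seconds.
#' @param per_trial return the per-trial rates instead of their mean.
#' @return rate in Hz (or per-trial vector).
#' @export
baseline_rate <- function(neuron, events, window_s = c(-0.5, 0),
                          per_trial = FALSE) {
  trials <- completed_trials(events)
  trials <- trials[!is.na(trials$t_start_cue), , drop = FALSE]
  stop_if(nrow(trials) == 0L, "no completed trials with a start cue")
  counts <- count_in_window(neuron$spike_times,
                            trials$t_start_cue + window_s[1],
                            trials$t_start_cue + window_s[2])
  rates <- counts / diff(window_s)
  if (per_trial) rates else mean(rates)
}

event_time_column <- function(event) {
  switch(event,
    start_cue = "t_start_cue", cost_cue = "t_cost_cue",
    fixation_target = "t_fixation_target", reward_cue = "t_reward_cue",
    beep = "t_beep", delivery = "t_outcome",
    unpredictable_reward = "t_outcome", airpuff = "t_outcome",
    stop("unknown event: ", event))
}

event_trials <- function(events, event) {
  types <- switch(event,
    unpredictable_reward = "unpredictable_reward",
    airpuff = "unpredictable_airpuff",
    "saccade")
  completed_trials(events, types = types)
}

#' Per-trial normalized response of a neuron to a task event
#'
#' Firing rate inside the event's analysis window minus the neuron's
#' spontaneous rate (subtraction convention, in Hz; a ratio mode is
#' available). Only trials completed without errors are analyzed; trials
#' missing the event are dropped.
#'
#' @param neuron a `neuron_record`.
#' @param events a `session_events` table.
#' @param event event name (`"cost_cue"`, `"reward_cue"`, `"delivery"`,
#'   `"unpredictable_reward"`, `"airpuff"`, ...).
#' @param window `c(start, end)` in ms relative to event onset (half-open),
#'   e.g. one entry of [response_windows()].
#' @param normalization `"difference"` (Hz above baseline, default) or
#'   `"ratio"` (rate / baseline).
#' @param baseline `"neuron"` (session-mean spontaneous rate, default) or
#'   `"trial"` (that trial's own pre-start-cue rate).
#' @return data frame `trial_id`, `cost_condition`, `reward_condition`,
#'   `rewarded`, `response` with attribute `baseline_hz`.
#' @export
event_response <- function(neuron, events, event, window,
                           normalization = c("difference", "ratio"),
                           baseline = c("neuron", "trial")) {
  normalization <- match.arg(normalization)
  baseline <- match.arg(baseline)
  stop_if(window[1] >= window[2], "window start must precede its end")
  trials <- event_trials(events, event)
  col <- event_time_column(event)
  trials <- trials[!is.na(trials[[col]]), , drop = FALSE]
  stop_if(nrow(trials) == 0L, "no analyzable trials for event ", event)
  t_ev <- trials[[col]]
  counts <- count_in_window(neuron$spike_times,
                            t_ev + window[1] / 1000,
                            t_ev + window[2] / 1000)
  rate <- counts / (diff(window) / 1000)
  base <- if (baseline == "neuron") {
    baseline_rate(neuron, events)
  } else {
    stop_if(any(is.na(trials$t_start_cue)),
            "per-trial baseline needs a start cue on every analyzed trial")
    count_in_window(neuron$spike_times, trials$t_start_cue - 0.5,
                    trials$t_start_cue) / 0.5
  }
  resp <- switch(normalization,
    difference = rate - base,
    ratio = rate / ifelse(base == 0, NA_real_, base))
  out <- data.frame(trial_id = trials$trial_id,
                    cost_condition = trials$cost_condition,
                    reward_condition = trials$reward_condition,
                    rewarded = trials$rewarded,
                    response = resp,
                    stringsAsFactors = FALSE)
  attr(out, "baseline_hz") <- if (baseline == "neuron") base else mean(base)
  out
}

#' Criteria for identifying a putative dopamine neuron
#'
#' @param max_tonic_rate tonic firing-rate ceiling, Hz (exclusive).
#' @param min_waveform_duration spike-waveform duration floor, microseconds
#'   (exclusive).
#' @param alpha significance level of the unpredictable-reward response
#'   test.
#' @return an `identification_criteria` list.
#' @export
identification_criteria <- function(max_tonic_rate = 6,
                                    min_waveform_duration = 300,
                                    alpha = 0.05) {
  check_number(max_tonic_rate, "max_tonic_rate", lower = 0, strict_lower = TRUE)
  check_number(min_waveform_duration, "min_waveform_duration", lower = 0,
               strict_lower = TRUE)
  check_probability(alpha, "alpha")
  structure(list(max_tonic_rate = max_tonic_rate,
                 min_waveform_duration = min_waveform_duration,
                 alpha = alpha),
            class = "identification_criteria")
}

#' Identify a putative dopamine neuron
#'
#' Accepts a neuron if all three electrophysiological criteria hold: a low
#' tonic firing rate (< 6 Hz, measured as total spikes over the recorded
#' span), a long spike waveform (> 300 us), and a significant phasic
#' activation to unpredicted reward (one-sided signed-rank test of the
#' per-trial windowed response against zero).
#'
#' @param neuron a `neuron_record`.
#' @param events a `session_events` table containing unpredictable-reward
#'   trials.
#' @param criteria an [identification_criteria()].
#' @param windows window list from [response_windows()].
#' @return list with `accept`, the individual criterion results and the
#'   measured metrics; `accept` is `NA` (flagged indeterminate) when no
#'   unpredictable-reward trials exist.
#' @export
identify_dopamine_neuron <- function(neuron, events,
                                     criteria = identification_criteria(),
                                     windows = response_windows("P")) {
  span <- max(events$t_trial_end) - min(events$t_trial_start)
  tonic <- length(neuron$spike_times) / span
  tonic_ok <- tonic < criteria$max_tonic_rate
  waveform_ok <- neuron$waveform_duration_us > criteria$min_waveform_duration
  ur <- events[events$trial_type == "unpredictable_reward", , drop = FALSE]
  if (nrow(ur) == 0L) {
    return(list(accept = NA, tonic_rate_hz = tonic, tonic_ok = tonic_ok,
                waveform_ok = waveform_ok, reward_response_p = NA_real_,
                indeterminate = TRUE))
  }
  # paired per-trial comparison: delivery-window rate vs the rate in the
  # 500 ms immediately preceding the (uncued) delivery of the same trial
  win <- windows$unpredictable_reward
  rate_win <- count_in_window(neuron$spike_times,
                              ur$t_outcome + win[1] / 1000,
                              ur$t_outcome + win[2] / 1000) /
    (diff(win) / 1000)
  rate_pre <- count_in_window(neuron$spike_times,
                              ur$t_outcome - 0.5, ur$t_outcome) / 0.5
  test <- suppressWarnings(
    wilcoxon_signed_rank(rate_win, rate_pre, alternative = "greater"))
  reward_ok <- !is.na(test$p_value) && test$p_value < criteria$alpha
  list(accept = tonic_ok && waveform_ok && reward_ok,
       tonic_rate_hz = tonic, tonic_ok = tonic_ok,
       waveform_ok = waveform_ok,
       reward_response_p = test$p_value,
       mean_reward_response = mean(rate_win - rate_pre),
       indeterminate = FALSE)
}

#' Classify a dopamine neuron as motivational value or salience type
#'
#' The mean normalized response to the aversive air-puff decides the
#' subtype: below the spontaneous rate (negative normalized response) is
#' "value", above is "salience"; exact equality is flagged unclassified.
#'
#' @param neuron a `neuron_record`.
#' @param events a `session_events` table with air-puff trials.
#' @param window air-puff window in ms, e.g. `response_windows("P")$airpuff`.
#' @return list with `subtype` (`"value"`, `"salience"` or
#'   `"unclassified"`) and `mean_airpuff_response`.
#' @export
classify_neuron_subtype <- function(neuron, events,
                                    window = response_windows("P")$airpuff) {
  ap <- events[events$trial_type == "unpredictable_airpuff", , drop = FALSE]
  if (nrow(ap) == 0L) {
    return(list(subtype = "indeterminate", mean_airpuff_response = NA_real_))
  }
  resp <- event_response(neuron, events, "airpuff", window)
  m <- mean(resp$response)
  subtype <- if (m < 0) "value" else if (m > 0) "salience" else "unclassified"
  list(subtype = subtype, mean_airpuff_response = m)
}
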