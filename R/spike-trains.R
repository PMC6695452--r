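#' Build the event-locked rate-bump table for a session
#'
#' Resolves a neuron profile against a session's event table: one row per
#' (response row, matching trial) with the absolute bump center (s),
#' width (s) and condition-resolved amplitude (Hz). Bumps attach to events
#' that actually occurred (e.g. no reward-cue bump on aborted trials).
#' @noRd
bump_table <- function(profile, events) {
  event_times <- function(evname) {
    switch(evname,
      start_cue = events$t_start_cue,
      cost_cue = events$t_cost_cue,
      fixation_target = events$t_fixation_target,
      reward_cue = events$t_reward_cue,
      beep = events$t_beep,
      delivery = ifelse(events$trial_type == "saccade", events$t_outcome,
                        NA_real_),
      unpredictable_reward = ifelse(events$trial_type == "unpredictable_reward",
                                    events$t_outcome, NA_real_),
      airpuff = ifelse(events$trial_type == "unpredictable_airpuff",
                       events$t_outcome, NA_real_),
      stop("unknown response event: ", evname)
    )
  }
  out <- list()
  for (i in seq_len(nrow(profile$responses))) {
    r <- profile$responses[i, ]
    t_ev <- event_times(r$event)
    keep <- !is.na(t_ev)
    if (!is.na(r$reward_condition)) {
      keep <- keep & !is.na(events$reward_condition) &
        events$reward_condition == r$reward_condition
    }
    if (!is.na(r$rewarded)) {
      keep <- keep & !is.na(events$rewarded) & events$rewarded == r$rewarded
    }
    if (!any(keep)) next
    amp <- rep(r$amplitude_hz, sum(keep))
    is_hc <- !is.na(events$cost_condition[keep]) &
      events$cost_condition[keep] == "HC"
    amp[is_hc] <- amp[is_hc] * r$cost_factor
    out[[length(out) + 1L]] <- data.frame(
      center = t_ev[keep] + r$latency_ms / 1000,
      width = r$width_ms / 1000,
      amplitude = amp
    )
  }
  if (length(out) == 0L) {
    return(data.frame(center = numeric(), width = numeric(),
                      amplitude = numeric()))
  }
  do.call(rbind, out)
}

# instantaneous rate (Hz) at sorted times, clipped at zero; bump support
# truncated at +/- 4 widths
rate_at_times <- function(times, baseline, bumps, support = 4) {
  r <- rep(baseline, length(times))
  for (i in seq_len(nrow(bumps))) {
    c0 <- bumps$center[i]; w <- bumps$width[i]
    lo <- findInterval(c0 - support * w, times) + 1L
    hi <- findInterval(c0 + support * w, times)
    if (hi < lo) next
    idx <- lo:hi
    r[idx] <- r[idx] + bumps$amplitude[i] *
      exp(-(times[idx] - c0)^2 / (2 * w^2))
  }
  pmax(r, 0)
}

#' Simulate a spike train for one neuron over one session
#'
#' Inhomogeneous-Poisson spikes with rate
#' `rate(t) = max(0, baseline + sum of event-locked Gaussian bumps)`,
#' generated by thinning: candidate spikes are drawn from a homogeneous
#' process at an upper bound on the rate and accepted with probability
#' `rate(t) / bound`. This is exact for the (tail-truncated) closed-form
#' rate function; no time binning is involved.
#'
#' @param profile a [neuron_profile()].
#' @param events a `session_events` table.
#' @param seed integer seed.
#' @param t_range time span to simulate, defaults to the session span.
#' @return a `neuron_record` list: `neuron_id`, `spike_times` (sorted,
#'   seconds on the session clock), `waveform_duration_us`, and the true
#'   `subtype` kept as ground-truth metadata.
#' @export
generate_spike_trains <- function(profile, events, seed = 1L,
                                  t_range = NULL) {
  stop_if(!inherits(profile, "neuron_profile"), "`profile` must be a neuron_profile")
  if (is.null(t_range)) t_range <- c(0, max(events$t_trial_end))
  bumps <- bump_table(profile, events)
  lam_max <- profile$baseline_rate +
    sum(pmax(profile$responses$amplitude_hz, 0) *
          pmax(profile$responses$cost_factor, 1))
  spikes <- with_local_seed(seed, {
    if (lam_max <= 0) {
      numeric(0)
    } else {
      span <- diff(t_range)
      n_cand <- rpois(1, lam_max * span)
      if (n_cand == 0L) {
        numeric(0)
      } else {
        cand <- sort(runif(n_cand, t_range[1], t_range[2]))
        rate <- rate_at_times(cand, profile$baseline_rate, bumps)
        cand[runif(n_cand) < rate / lam_max]
      }
    }
  })
  structure(list(neuron_id = profile$neuron_id,
                 spike_times = spikes,
                 waveform_duration_us = profile$waveform_duration_us,
                 subtype = profile$subtype),
            class = "neuron_record")
}

#' @export
print.neuron_record <- function(x, ...) {
  cat(sprintf("<neuron_record> %s: %d spikes, waveform %g us\n",
              x$neuron_id, length(x$spike_times), x$waveform_duration_us))
  invisible(x)
}
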