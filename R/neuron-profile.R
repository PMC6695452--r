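#' Generative profile of a simulated midbrain dopamine neuron
#'
#' A neuron is a baseline Poisson rate plus event-locked Gaussian rate
#' bumps. Each response row gives the bump amplitude (Hz, negative for
#' suppression), latency and width (SD, ms) for one (event, condition)
#' combination; `cost_mod` multiplies the amplitude on high-cost trials,
#' which is how paid/predicted cost modulates the response. Subtypes
#' differ in the air-puff response: "value" neurons are suppressed by the
#' aversive stimulus, "salience" neurons are excited by it.
#'
#' @param neuron_id identifier.
#' @param subtype `"value"` or `"salience"`.
#' @param baseline_rate spontaneous rate, Hz (>= 0).
#' @param waveform_duration_us spike waveform duration metadata, microseconds.
#' @param responses data frame of response rows; `NULL` uses
#'   [default_response_table()] for the subtype/task.
#' @param cost_modulation named multipliers (HC relative to LC) for
#'   `cost_cue`, `reward_pos_cue`, `reward_neg_cue`, `delivery`.
#' @param task_kind which task the default response table targets.
#' @return a `neuron_profile` list.
#' @export
neuron_profile <- function(neuron_id = "n001",
                           subtype = c("value", "salience"),
                           baseline_rate = 5,
                           waveform_duration_us = 350,
                           responses = NULL,
                           cost_modulation = default_cost_modulation(),
                           task_kind = c("saccade", "uncertain")) {
  subtype <- match.arg(subtype)
  task_kind <- match.arg(task_kind)
  check_number(baseline_rate, "baseline_rate", lower = 0)
  check_number(waveform_duration_us, "waveform_duration_us", lower = 0,
               strict_lower = TRUE)
  cm <- modifyList(default_cost_modulation(), as.list(cost_modulation))
  if (is.null(responses)) {
    responses <- default_response_table(subtype, task_kind, cm)
  }
  needed <- c("event", "reward_condition", "rewarded", "amplitude_hz",
              "latency_ms", "width_ms", "cost_factor")
  stop_if(!all(needed %in% names(responses)),
          "`responses` must have columns: ", paste(needed, collapse = ", "))
  stop_if(any(responses$latency_ms < 0) || any(responses$width_ms <= 0),
          "response latencies must be >= 0 and widths > 0")
  structure(list(neuron_id = neuron_id, subtype = subtype,
                 baseline_rate = baseline_rate,
                 waveform_duration_us = waveform_duration_us,
                 responses = responses, cost_modulation = cm),
            class = "neuron_profile")
}

#' @rdname neuron_profile
#' @export
default_cost_modulation <- function() {
  list(cost_cue = 0.6, reward_pos_cue = 1.3, reward_neg_cue = 1.0,
       delivery = 1.3)
}

#' Default event-locked response rows for a dopamine-like neuron
#'
#' Encodes the canonical response pattern: phasic activation to reward
#' cues and unpredicted reward, suppression to no-reward cues, a modest
#' cost-cue response that is weaker on high-cost trials, and an air-puff
#' response whose sign defines the subtype. In the uncertain task the
#' reward cue is not reward-predictive (no response) and the delivery
#' itself drives an RPE-like response on rewarded trials.
#'
#' @param subtype `"value"` or `"salience"`.
#' @param task_kind `"saccade"` or `"uncertain"`.
#' @param cost_modulation multiplier list, see [default_cost_modulation()].
#' @return response data frame usable in [neuron_profile()].
#' @export
default_response_table <- function(subtype = "value", task_kind = "saccade",
                                   cost_modulation = default_cost_modulation()) {
  cm <- cost_modulation
  row <- function(event, rwd_cond, rewarded, amp, lat, width, fac) {
    data.frame(event = event, reward_condition = rwd_cond,
               rewarded = rewarded, amplitude_hz = amp, latency_ms = lat,
               width_ms = width, cost_factor = fac,
               stringsAsFactors = FALSE)
  }
  airpuff_amp <- if (subtype == "value") -3 else 5
  tab <- rbind(
    row("start_cue", NA, NA, -1, 250, 50, 1),
    row("cost_cue", NA, NA, 6, 200, 40, cm$cost_cue),
    row("unpredictable_reward", NA, NA, 8, 180, 45, 1),
    row("airpuff", NA, NA, airpuff_amp, 120, 40, 1)
  )
  if (task_kind == "saccade") {
    tab <- rbind(tab,
      row("reward_cue", "R+", NA, 8, 220, 45, cm$reward_pos_cue),
      row("reward_cue", "R-", NA, -3, 220, 45, cm$reward_neg_cue))
  } else {
    tab <- rbind(tab,
      row("delivery", NA, 1L, 8, 300, 50, cm$delivery),
      row("delivery", NA, 0L, -3, 300, 50, 1))
  }
  tab
}
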