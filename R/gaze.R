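#' Default saccade-latency model for gaze simulation
#'
#' Mean/SD (ms) of saccade latency per (event, condition). The defaults
#' encode the behavioural pattern the pipeline is meant to detect: faster
#' saccades to the LC than the HC cost cue (preference for the low-cost
#' condition), faster saccades to R+ than R- cues, and faster saccades to
#' HC than LC reward cues (higher valuation after paid cost).
#'
#' @param task_kind task variant; the uncertain task has a single reward
#'   cue per condition with no RT difference.
#' @return data frame with columns `event`, `cost_condition`,
#'   `reward_condition`, `mean_ms`, `sd_ms`.
#' @export
default_rt_model <- function(task_kind = "saccade") {
  base <- data.frame(
    event = c("cost_cue", "cost_cue"),
    cost_condition = c("HC", "LC"),
    reward_condition = NA_character_,
    mean_ms = c(250, 220),
    sd_ms = 20,
    stringsAsFactors = FALSE
  )
  rc <- if (task_kind == "uncertain") {
    data.frame(event = "reward_cue", cost_condition = c("HC", "LC"),
               reward_condition = "uncertain", mean_ms = c(210, 210),
               sd_ms = 20, stringsAsFactors = FALSE)
  } else {
    data.frame(event = "reward_cue",
               cost_condition = c("HC", "LC", "HC", "LC"),
               reward_condition = c("R+", "R+", "R-", "R-"),
               mean_ms = c(180, 195, 225, 240),
               sd_ms = 15, stringsAsFactors = FALSE)
  }
  rbind(base, rc)
}

lookup_latency <- function(rt_model, event, cost, rwd) {
  rows <- rt_model$event == event &
    (is.na(rt_model$cost_condition) | rt_model$cost_condition == cost) &
    (is.na(rt_model$reward_condition) | is.na(rwd) |
       rt_model$reward_condition == rwd)
  if (!any(rows)) return(NULL)
  rt_model[which(rows)[1], c("mean_ms", "sd_ms")]
}

#' Simulate a 500 Hz two-channel gaze trace for a session
#'
#' Noisy fixation epochs with step-like saccades to cue locations at
#' latencies drawn from `rt_model`. A saccade is an instantaneous change of
#' the target position followed by a short exponential settle; only onset
#' detectability is modelled, not realistic saccade kinematics. True onset
#' times are attached as the `"onsets"` attribute for round-trip tests.
#'
#' @param events a `session_events` table.
#' @param rt_model latency table as from [default_rt_model()]; `NULL`
#'   programs no saccades at all (stationary noise).
#' @param noise_sd gaze position noise SD in degrees (> 0).
#' @param sampling_rate samples per second (default 500).
#' @param seed integer seed.
#' @param saccade_amplitude step size in degrees toward a cue.
#' @param settle_tau_ms time constant of the post-step settle.
#' @return a `gaze_trace` data frame (`time_s`, `x_deg`, `y_deg`) with
#'   attributes `sampling_rate` and `onsets`.
#' @export
generate_gaze_trace <- function(events, rt_model = default_rt_model(),
                                noise_sd = 0.1, sampling_rate = 500,
                                seed = 1L, saccade_amplitude = 10,
                                settle_tau_ms = 4) {
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  with_local_seed(seed, {
    t_end <- max(events$t_trial_end) + 0.5
    n <- floor(t_end * sampling_rate) + 1L
    tt <- (seq_len(n) - 1L) / sampling_rate

    steps <- data.frame(time = 0, x = 0, y = 0)
    onsets <- data.frame(trial_id = integer(), event = character(),
                         t_cue = numeric(), t_onset = numeric(),
                         stringsAsFactors = FALSE)
    add_step <- function(time, x, y) {
      steps[nrow(steps) + 1L, ] <<- list(time, x, y)
    }
    if (!is.null(rt_model)) {
      sac <- events[events$trial_type == "saccade", , drop = FALSE]
      for (i in seq_len(nrow(sac))) {
        tr <- sac[i, ]
        for (ev in c("cost_cue", "reward_cue")) {
          cue <- tr[[paste0("t_", ev)]]
          if (is.na(cue)) next
          lat <- lookup_latency(rt_model, ev, tr$cost_condition,
                                tr$reward_condition)
          if (is.null(lat)) next
          l_s <- max(rnorm(1, lat$mean_ms, lat$sd_ms), 40) / 1000
          tgt <- if (ev == "cost_cue") c(saccade_amplitude, 0)
                 else c(-saccade_amplitude, 0)
          add_step(cue + l_s, tgt[1], tgt[2])
          onsets[nrow(onsets) + 1L, ] <- list(tr$trial_id, ev, cue, cue + l_s)
          # return to fixation after the cue epoch
          ret <- if (ev == "cost_cue" && !is.na(tr$t_fixation_target)) {
            tr$t_fixation_target + 0.2
          } else if (ev == "reward_cue") {
            tr$t_trial_end
          } else NA_real_
          if (!is.na(ret)) add_step(ret, 0, 0)
        }
      }
    }
    steps <- steps[order(steps$time), , drop = FALSE]
    seg <- findInterval(tt, steps$time)
    seg[seg < 1L] <- 1L
    x_tgt <- steps$x[seg]
    y_tgt <- steps$y[seg]
    # exponential settle toward the instantaneous target
    a <- 1 - exp(-(1000 / sampling_rate) / settle_tau_ms)
    x <- as.numeric(stats::filter(a * x_tgt, 1 - a, method = "recursive"))
    y <- as.numeric(stats::filter(a * y_tgt, 1 - a, method = "recursive"))
    trace <- data.frame(time_s = tt,
                        x_deg = x + rnorm(n, 0, noise_sd),
                        y_deg = y + rnorm(n, 0, noise_sd))
    attr(trace, "sampling_rate") <- sampling_rate
    attr(trace, "onsets") <- onsets
    class(trace) <- c("gaze_trace", "data.frame")
    trace
  })
}
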