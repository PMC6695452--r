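#' Generate a per-trial event table for one session
#'
#' Lays out the within-trial epochs of the HLC tasks on a common session
#' clock (seconds):
#' start cue (750 ms) -> cost cue (750 ms) -> fixation epoch (HC: long
#' fixation target; LC: blank then 500 ms target) -> reward cue -> beep
#' 750 ms after the reward cue, with water delivered at the beep on
#' rewarded trials. Forced aborts terminate an LC trial 100 ms before the
#' reward cue would have appeared; spontaneous fixation-break aborts occur
#' on HC trials at a configurable rate. Uncued reward and air-puff trials
#' carry only a delivery event.
#'
#' Trial order is uniformly randomized. Within each cost condition the
#' saccade task assigns half R+ and half R- cues; the uncertain task
#' rewards exactly half of the completed-trial slots per condition.
#'
#' @param spec a [task_spec()].
#' @param seed integer seed; the table is a pure function of `(spec, seed)`.
#' @return a `session_events` data frame, one row per trial, with event
#'   times in seconds (`NA` for events that never happened on that trial)
#'   and logical `aborted` / `forced_abort` flags.
#' @export
generate_session_events <- function(spec, seed = 1L) {
  stop_if(!inherits(spec, "task_spec"), "`spec` must be a task_spec")
  with_local_seed(seed, {
    n <- spec$n_trials_per_condition
    n_sac <- 2L * n
    type <- c(rep("saccade", n_sac),
              rep("unpredictable_reward", spec$n_unpredictable_reward),
              rep("unpredictable_airpuff", spec$n_unpredictable_airpuff))
    n_tot <- length(type)

    cost <- rep(NA_character_, n_tot)
    cost[seq_len(n_sac)] <- sample(rep(c("HC", "LC"), each = n))

    half_split <- function(labels, k) sample(rep(labels, length.out = k))
    rwd_cond <- rep(NA_character_, n_tot)
    rewarded <- rep(NA_integer_, n_tot)
    is_sac <- type == "saccade"
    if (spec$task_kind == "saccade") {
      for (cc in c("HC", "LC")) {
        idx <- which(is_sac & cost == cc)
        rwd_cond[idx] <- half_split(c("R+", "R-"), length(idx))
      }
      rewarded[is_sac] <- as.integer(rwd_cond[is_sac] == "R+")
    } else if (spec$task_kind == "uncertain") {
      rwd_cond[is_sac] <- "uncertain"
      for (cc in c("HC", "LC")) {
        idx <- which(is_sac & cost == cc)
        n_r <- round(spec$reward_prob_uncertain * length(idx))
        rewarded[idx] <- sample(rep(c(1L, 0L), c(n_r, length(idx) - n_r)))
      }
    } else { # exploration: the reward cue is a choice, resolved by the
             # choice generator; event scaffold only
      rwd_cond[is_sac] <- "choice"
      rewarded[is_sac] <- NA_integer_
    }
    rewarded[type == "unpredictable_reward"] <- 1L
    rewarded[type == "unpredictable_airpuff"] <- 0L

    forced <- is_sac & cost == "LC" &
      runif(n_tot) < spec$forced_abort_rate_lc
    hc_abort <- is_sac & cost == "HC" & !forced &
      runif(n_tot) < spec$abort_rate_hc
    aborted <- forced | hc_abort
    rewarded[aborted] <- 0L

    ord <- sample.int(n_tot)
    type <- type[ord]; cost <- cost[ord]; rwd_cond <- rwd_cond[ord]
    rewarded <- rewarded[ord]; forced <- forced[ord]; aborted <- aborted[ord]
    is_sac <- type == "saccade"

    sc_dur <- spec$start_cue_duration / 1000
    cc_dur <- spec$cost_cue_duration / 1000
    fix_hc <- spec$fixation_duration_hc / 1000
    blank_lc <- spec$blank_duration_lc / 1000
    tgt_lc <- spec$lc_target_duration / 1000
    beep_delay <- spec$beep_delay / 1000

    # within-trial offsets (relative to trial start)
    o_start <- ifelse(is_sac, 0, NA_real_)
    o_cost  <- ifelse(is_sac, sc_dur, NA_real_)
    o_fix   <- ifelse(is_sac,
                      sc_dur + cc_dur + ifelse(cost == "HC", 0, blank_lc),
                      NA_real_)
    o_rcue  <- ifelse(is_sac,
                      sc_dur + cc_dur + ifelse(cost == "HC", fix_hc, blank_lc + tgt_lc),
                      NA_real_)
    o_beep  <- o_rcue + beep_delay
    o_out   <- ifelse(is_sac, o_beep, 0.5)

    o_abort <- rep(NA_real_, n_tot)
    o_abort[forced] <- o_rcue[forced] - 0.1
    if (any(hc <- aborted & !forced)) {
      # fixation break somewhere after the fixation window arms (400 ms in)
      lo <- o_fix[hc] + 0.4
      o_abort[hc] <- lo + runif(sum(hc)) * (o_rcue[hc] - lo)
    }
    o_rcue[aborted] <- NA_real_
    o_beep[aborted] <- NA_real_
    o_out[aborted & is_sac] <- NA_real_

    o_end <- ifelse(is_sac,
                    ifelse(aborted, o_abort + 0.5, o_out + 0.8),
                    o_out + 1.0)
    t0 <- cumsum(c(0, (o_end + spec$iti_s)[-n_tot]))

    ev <- data.frame(
      trial_id = seq_len(n_tot),
      trial_type = type,
      cost_condition = cost,
      reward_condition = rwd_cond,
      rewarded = rewarded,
      aborted = aborted,
      forced_abort = forced,
      t_trial_start = t0,
      t_start_cue = t0 + o_start,
      t_cost_cue = t0 + o_cost,
      t_fixation_target = t0 + o_fix,
      t_reward_cue = t0 + o_rcue,
      t_beep = t0 + o_beep,
      t_outcome = t0 + o_out,
      t_abort = t0 + o_abort,
      t_trial_end = t0 + o_end,
      stringsAsFactors = FALSE
    )
    attr(ev, "task_spec") <- spec
    attr(ev, "seed") <- as.integer(seed)
    class(ev) <- c("session_events", "data.frame")
    ev
  })
}

#' Keep only trials completed without any error
#'
#' Error-free completed trials are the analysis set for every neural and
#' reaction-time measure; aborted trials (including forced aborts) are
#' excluded.
#' @param events a `session_events` table.
#' @param types trial types to keep (default `"saccade"`).
#' @return the filtered table.
#' @export
completed_trials <- function(events, types = "saccade") {
  events[!events$aborted & events$trial_type %in% types, , drop = FALSE]
}
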