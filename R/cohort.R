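#' Write a full synthetic cohort to disk
#'
#' Generates the raw inputs of the analysis pipeline — trial event tables,
#' spike trains, behavioural choice sessions and (optionally) gaze traces
#' — and serializes them in plain-text form together with a ground-truth
#' manifest:
#' \describe{
#'   \item{`trials.csv`}{one row per trial across all neuron sessions
#'     (times in seconds, 6-decimal fixed point).}
#'   \item{`spikes.csv`}{long format `neuron_id`, `spike_time_s`.}
#'   \item{`gaze.csv`}{`session_id`, `time_s`, `x_deg`, `y_deg` for the
#'     first `max_gaze_sessions` sessions (gaze traces are bulky).}
#'   \item{`behavior_sessions.csv`}{exploration-task choices.}
#'   \item{`manifest.yaml`}{seeds, configuration and all generating
#'     parameters (neuron subtypes, true RL parameters, true saccade
#'     onsets). The analysis functions never read the manifest; ground
#'     truth is hidden by interface, not deleted.}
#' }
#' Identical `(config, seed)` produce byte-identical files.
#'
#' @param config a `run_config`, see [default_run_config()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param max_gaze_sessions number of sessions whose gaze trace is written.
#' @return invisibly, the manifest list.
#' @export
build_cohort <- function(config = default_run_config(), out_dir, seed = 1L,
                         max_gaze_sessions = 1L) {
  errs <- validate_config(config)
  stop_if(length(errs) > 0,
          "invalid config:\n", paste("-", errs, collapse = "\n"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(out_dir), "cannot create output directory: ", out_dir)

  fixed6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  sac_spec <- task_spec("saccade")
  n_value <- round(config$prop_value * config$n_neurons)

  trials <- list(); spikes <- list(); gaze <- list(); truth_neurons <- list()
  for (i in seq_len(config$n_neurons)) {
    ev <- generate_session_events(sac_spec, seed = derive_seed(seed, 2000 + 2 * i))
    subtype <- if (i <= n_value) "value" else "salience"
    prof <- neuron_profile(sprintf("n%03d", i), subtype = subtype,
                           baseline_rate = config$baseline_rate,
                           waveform_duration_us = config$waveform_duration_us,
                           cost_modulation = config$cost_modulation,
                           task_kind = "saccade")
    rec <- generate_spike_trains(prof, ev, seed = derive_seed(seed, 2001 + 2 * i))
    sid <- sprintf("s%03d", i)
    tr <- as.data.frame(ev)
    time_cols <- grep("^t_", names(tr), value = TRUE)
    for (cl in time_cols) tr[[cl]] <- fixed6(tr[[cl]])
    trials[[i]] <- cbind(session_id = sid, tr)
    spikes[[i]] <- data.frame(neuron_id = rec$neuron_id,
                              spike_time_s = fixed6(rec$spike_times))
    truth_neurons[[i]] <- list(neuron_id = rec$neuron_id, session_id = sid,
                               subtype = subtype,
                               baseline_rate = config$baseline_rate,
                               waveform_duration_us = config$waveform_duration_us)
    if (i <= max_gaze_sessions) {
      g <- generate_gaze_trace(ev, rt_model = config$rt_model,
                               seed = derive_seed(seed, 6000 + i))
      gaze[[i]] <- data.frame(session_id = sid,
                              time_s = fixed6(g$time_s),
                              x_deg = sprintf("%.4f", g$x_deg),
                              y_deg = sprintf("%.4f", g$y_deg))
    }
  }

  exp_spec <- task_spec("exploration")
  behav <- lapply(seq_len(config$n_exploration_sessions), function(i) {
    ses <- generate_exploration_choices(config$true_rl_params, exp_spec,
                                        seed = derive_seed(seed, 4000 + i))
    cbind(session_id = sprintf("b%03d", i),
          as.data.frame(ses)[, c("trial", "cost_condition", "chosen",
                                 "rewarded", "correct")])
  })

  write_one <- function(rows, file) {
    df <- if (length(rows)) do.call(rbind, rows) else data.frame()
    write.csv(df, file.path(out_dir, file), row.names = FALSE, quote = FALSE)
  }
  write_one(trials, "trials.csv")
  write_one(spikes, "spikes.csv")
  write_one(gaze, "gaze.csv")
  write_one(behav, "behavior_sessions.csv")

  manifest <- list(
    seed = as.integer(seed),
    n_neurons = config$n_neurons,
    n_exploration_sessions = config$n_exploration_sessions,
    effects_on = config$effects_on,
    true_rl_params = unclass(config$true_rl_params),
    cost_modulation = config$cost_modulation,
    prop_value = config$prop_value,
    baseline_rate = config$baseline_rate,
    waveform_duration_us = config$waveform_duration_us,
    neurons = truth_neurons
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
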