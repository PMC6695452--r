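test_that("degenerate latency model places onsets exactly at mean latency", {
  ev <- generate_session_events(task_spec("saccade", n_trials_per_condition = 5L,
                                          n_unpredictable_reward = 0L,
                                          n_unpredictable_airpuff = 0L,
                                          abort_rate_hc = 0,
                                          forced_abort_rate_lc = 0), seed = 2)
  m <- default_rt_model()
  m$sd_ms <- 0
  m$mean_ms <- 200
  tr <- generate_gaze_trace(ev, rt_model = m, seed = 3)
  on <- attr(tr, "onsets")
  expect_true(all(abs((on$t_onset - on$t_cue) - 0.2) < 1e-9))
})

test_that("detector recovers programmed onsets within one sample at high SNR", {
  ev <- generate_session_events(task_spec("saccade", n_trials_per_condition = 10L,
                                          n_unpredictable_reward = 0L,
                                          n_unpredictable_airpuff = 0L,
                                          abort_rate_hc = 0,
                                          forced_abort_rate_lc = 0), seed = 5)
  tr <- generate_gaze_trace(ev, noise_sd = 0.1, seed = 6)
  on <- attr(tr, "onsets")
  errs <- vapply(seq_len(nrow(on)), function(i) {
    det <- detect_saccade_onset(tr, on$t_cue[i])
    (det - on$t_onset[i]) * 1000
  }, numeric(1))
  expect_true(all(abs(errs) <= 10))
  expect_true(all(errs >= 0))  # detection cannot precede the step
})

test_that("stationary noise yields no onset and zero-variance baselines warn", {
  ev <- tiny_events(20)
  tr <- generate_gaze_trace(ev, rt_model = NULL, noise_sd = 0.1, seed = 9)
  for (cue in c(2, 5, 8, 11, 14)) {
    expect_true(is.na(detect_saccade_onset(tr, cue)))
  }
  flat <- data.frame(time_s = seq(0, 2, by = 0.002),
                     x_deg = 0, y_deg = 0)
  expect_warning(res <- detect_saccade_onset(flat, 1), "degenerate")
  expect_true(is.na(res))
})

test_that("the threshold is five baseline SDs with a sustain requirement", {
  # constructed trace: known baseline SD, then a sustained plateau whose
  # deviation is a chosen multiple of the combined baseline SD
  make_trace <- function(mult, n_sustain = 50) {
    nb <- 100
    x <- rep(c(-0.1, 0.1), nb / 2)      # sd ~ 0.1005 in x, 0 in y
    s <- sqrt(var(x) + 0)
    data.frame(time_s = seq_len(nb + n_sustain) * 0.002,
               x_deg = c(x, rep(mult * sqrt(s^2), n_sustain) + 0),
               y_deg = 0)
  }
  cue <- 100 * 0.002 + 0.001
  tr_lo <- make_trace(4.9)
  tr_hi <- make_trace(5.1)
  expect_true(is.na(detect_saccade_onset(tr_lo, cue, baseline_window = 0.2)))
  expect_false(is.na(detect_saccade_onset(tr_hi, cue, baseline_window = 0.2)))
  # a single-sample excursion is rejected by the sustain criterion
  tr_spike <- make_trace(4.9)
  tr_spike$x_deg[101] <- 10
  expect_true(is.na(detect_saccade_onset(tr_spike, cue, baseline_window = 0.2)))
})

test_that("reaction-time tables exclude aborted trials and recover RT order", {
  spec <- task_spec("saccade", forced_abort_rate_lc = 0.3, abort_rate_hc = 0.2)
  ev <- generate_session_events(spec, seed = 31)
  tr <- generate_gaze_trace(ev, seed = 32)
  rt <- compute_reaction_times(ev, tr, "cost_cue")
  expect_true(all(rt$rt_ms > 0 & is.finite(rt$rt_ms)))
  expect_length(intersect(rt$trial_id, ev$trial_id[ev$aborted]), 0)
  # generator programs faster LC than HC cost-cue saccades
  expect_lt(mean(rt$rt_ms[rt$cost_condition == "LC"]),
            mean(rt$rt_ms[rt$cost_condition == "HC"]))
})
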