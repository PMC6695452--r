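test_that("baseline rate is a spike count over the pre-start-cue window", {
  ev <- generate_session_events(task_spec("saccade", abort_rate_hc = 0,
                                          forced_abort_rate_lc = 0), seed = 1)
  sac <- completed_trials(ev)
  # exactly 2 spikes in every 500 ms baseline window -> 4 Hz
  spikes <- sort(c(sac$t_start_cue - 0.4, sac$t_start_cue - 0.1))
  expect_equal(baseline_rate(fake_neuron(spikes), ev), 4)
  expect_equal(baseline_rate(fake_neuron(numeric(0)), ev), 0)
})

test_that("baseline estimate is unbiased for a Poisson neuron", {
  ev <- generate_session_events(task_spec("saccade", n_trials_per_condition = 50L,
                                          abort_rate_hc = 0,
                                          forced_abort_rate_lc = 0), seed = 2)
  prof <- neuron_profile("p", baseline_rate = 5)
  prof$responses$amplitude_hz <- 0
  rec <- generate_spike_trains(prof, ev, seed = 3)
  n_tr <- nrow(completed_trials(ev))
  se <- sqrt(5 / (0.5 * n_tr))
  expect_lt(abs(baseline_rate(rec, ev) - 5), 3 * se)
})

test_that("window responses recover the generated bump amplitude", {
  spec <- task_spec("saccade", n_trials_per_condition = 200L,
                    abort_rate_hc = 0, forced_abort_rate_lc = 0)
  ev <- generate_session_events(spec, seed = 4)
  prof <- neuron_profile("b", cost_modulation = list(reward_pos_cue = 1))
  rec <- generate_spike_trains(prof, ev, seed = 5)
  win <- response_windows("P")$reward_cue  # 140-350 ms
  resp <- event_response(rec, ev, "reward_cue", win)
  rp <- resp$response[resp$reward_condition == "R+"]
  # expected added rate: amplitude * Gaussian mass inside the window
  amp <- 8; lat <- 220; wd <- 45
  mass <- amp * wd * sqrt(2 * pi) *
    (pnorm((win[2] - lat) / wd) - pnorm((win[1] - lat) / wd)) / 1000
  expected <- mass / (diff(win) / 1000)
  expect_equal(mean(rp), expected, tolerance = 0.15 * expected)
})

test_that("responses are invariant to a uniform time shift", {
  ev <- generate_session_events(task_spec("saccade"), seed = 6)
  prof <- neuron_profile("s")
  rec <- generate_spike_trains(prof, ev, seed = 7)
  win <- response_windows("P")$cost_cue
  r0 <- event_response(rec, ev, "cost_cue", win)
  shift <- 123.456
  ev2 <- ev
  for (cl in grep("^t_", names(ev2), value = TRUE)) {
    ev2[[cl]] <- ev2[[cl]] + shift
  }
  rec2 <- rec
  rec2$spike_times <- rec2$spike_times + shift
  r1 <- event_response(rec2, ev2, "cost_cue", win)
  expect_equal(r0$response, r1$response)
})

test_that("identification applies each criterion", {
  ev <- generate_session_events(task_spec("saccade"), seed = 8)
  # tonic rate above 6 Hz -> reject
  hot <- neuron_profile("hot", baseline_rate = 8)
  rec_hot <- generate_spike_trains(hot, ev, seed = 9)
  expect_false(identify_dopamine_neuron(rec_hot, ev)$accept)
  # short waveform -> reject
  thin <- neuron_profile("thin", waveform_duration_us = 250)
  rec_thin <- generate_spike_trains(thin, ev, seed = 10)
  expect_false(identify_dopamine_neuron(rec_thin, ev)$accept)
  # default dopamine-like profile -> accept
  ok <- neuron_profile("ok")
  rec_ok <- generate_spike_trains(ok, ev, seed = 11)
  res <- identify_dopamine_neuron(rec_ok, ev)
  expect_true(res$accept)
  expect_lt(res$tonic_rate_hz, 6)
  # no unpredictable-reward trials -> indeterminate
  ev_none <- generate_session_events(
    task_spec("saccade", n_unpredictable_reward = 0L), seed = 12)
  rec2 <- generate_spike_trains(ok, ev_none, seed = 13)
  expect_true(identify_dopamine_neuron(rec2, ev_none)$indeterminate)
})

test_that("identification and subtype labels reach 95% accuracy at 50 trials", {
  spec <- task_spec("saccade", n_unpredictable_reward = 50L,
                    n_unpredictable_airpuff = 50L)
  n <- 40
  correct_subtype <- accepted <- logical(n)
  for (i in seq_len(n)) {
    subtype <- if (i %% 2 == 0) "value" else "salience"
    ev <- generate_session_events(spec, seed = 100 + i)
    prof <- neuron_profile(paste0("n", i), subtype = subtype)
    rec <- generate_spike_trains(prof, ev, seed = 200 + i)
    accepted[i] <- isTRUE(identify_dopamine_neuron(rec, ev)$accept)
    correct_subtype[i] <- classify_neuron_subtype(rec, ev)$subtype == subtype
  }
  expect_gte(mean(accepted), 0.95)
  expect_gte(mean(correct_subtype), 0.95)
})

test_that("subject-specific windows load from the packaged config", {
  wp <- response_windows("P")
  ws <- response_windows("S")
  expect_equal(wp$cost_cue, c(150, 300))
  expect_equal(ws$cost_cue, c(200, 400))
  expect_equal(wp$airpuff, c(30, 230))
  expect_equal(ws$delivery, c(200, 450))
  expect_error(response_windows("Q"), "unknown subject")
})
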