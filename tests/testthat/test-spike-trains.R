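test_that("a flat-rate profile produces Poisson counts at the right rate", {
  prof <- neuron_profile("flat", baseline_rate = 5)
  prof$responses$amplitude_hz <- 0
  ev <- tiny_events(1000)
  rec <- generate_spike_trains(prof, ev, seed = 1, t_range = c(0, 1000))
  lambda <- 5 * 1000
  expect_lt(abs(length(rec$spike_times) - lambda), 3 * sqrt(lambda))
  expect_true(!is.unsorted(rec$spike_times))
  expect_true(all(rec$spike_times >= 0))
})

test_that("zero baseline and zero amplitudes produce an empty train", {
  prof <- neuron_profile("silent", baseline_rate = 0)
  prof$responses$amplitude_hz <- 0
  rec <- generate_spike_trains(prof, tiny_events(100), seed = 2,
                               t_range = c(0, 100))
  expect_length(rec$spike_times, 0)
})

test_that("suppressive responses reduce the windowed rate below baseline", {
  spec <- task_spec("saccade", n_unpredictable_airpuff = 60L,
                    abort_rate_hc = 0, forced_abort_rate_lc = 0)
  ev <- generate_session_events(spec, seed = 3)
  prof <- neuron_profile("v", subtype = "value", baseline_rate = 8)
  rec <- generate_spike_trains(prof, ev, seed = 4)
  resp <- event_response(rec, ev, "airpuff", response_windows("P")$airpuff)
  expect_lt(mean(resp$response), 0)
})

test_that("invalid response geometry is rejected", {
  bad <- default_response_table()
  bad$width_ms[1] <- -10
  expect_error(neuron_profile("x", responses = bad), "width")
  bad2 <- default_response_table()
  bad2$latency_ms[2] <- -5
  expect_error(neuron_profile("x", responses = bad2), "latenc")
})

test_that("spike generation is deterministic given (profile, events, seed)", {
  ev <- generate_session_events(task_spec("saccade"), seed = 5)
  prof <- neuron_profile("d")
  a <- generate_spike_trains(prof, ev, seed = 10)
  b <- generate_spike_trains(prof, ev, seed = 10)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("cost modulation scales HC responses relative to LC", {
  spec <- task_spec("saccade", n_trials_per_condition = 150L,
                    abort_rate_hc = 0, forced_abort_rate_lc = 0)
  ev <- generate_session_events(spec, seed = 6)
  prof <- neuron_profile("m", cost_modulation = list(reward_pos_cue = 2))
  rec <- generate_spike_trains(prof, ev, seed = 7)
  resp <- event_response(rec, ev, "reward_cue", response_windows("P")$reward_cue)
  rp <- resp[resp$reward_condition == "R+", ]
  expect_gt(mean(rp$response[rp$cost_condition == "HC"]),
            mean(rp$response[rp$cost_condition == "LC"]))
})
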