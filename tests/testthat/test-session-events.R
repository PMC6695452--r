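test_that("session composition matches the task design", {
  ev <- generate_session_events(task_spec("saccade"), seed = 11)
  expect_equal(nrow(ev), 120)
  expect_equal(sum(ev$trial_type == "saccade"), 80)
  expect_equal(sum(ev$cost_condition == "HC", na.rm = TRUE), 40)
  expect_equal(sum(ev$cost_condition == "LC", na.rm = TRUE), 40)
  expect_equal(sum(ev$trial_type == "unpredictable_reward"), 20)
  expect_equal(sum(ev$trial_type == "unpredictable_airpuff"), 20)
  # half R+ / half R- within each cost condition
  for (cc in c("HC", "LC")) {
    sac <- ev[ev$trial_type == "saccade" & ev$cost_condition == cc, ]
    expect_equal(sum(sac$reward_condition == "R+"), 20)
  }
  # uncertain task: exactly half of the slots rewarded per condition
  evu <- generate_session_events(task_spec("uncertain"), seed = 3)
  for (cc in c("HC", "LC")) {
    sac <- evu[evu$trial_type == "saccade" & evu$cost_condition == cc, ]
    expect_equal(sum(sac$rewarded[!sac$aborted]) + sum(sac$rewarded[sac$aborted]),
                 sum(sac$rewarded))
  }
})

test_that("event times increase within every trial and flags are consistent", {
  for (seed in 1:5) {
    ev <- generate_session_events(task_spec("saccade"), seed = seed)
    for (i in seq_len(nrow(ev))) {
      times <- as.numeric(ev[i, c("t_start_cue", "t_cost_cue",
                                  "t_fixation_target", "t_reward_cue",
                                  "t_beep")])
      times <- times[!is.na(times)]
      expect_true(all(diff(times) > 0))
    }
    expect_true(all(ev$cost_condition[ev$forced_abort] == "LC"))
    expect_true(all(ev$rewarded[ev$aborted] == 0))
    expect_true(all(is.na(ev$t_reward_cue[ev$aborted])))
  }
})

test_that("forced-abort generation follows the configured rate", {
  ev0 <- generate_session_events(
    task_spec("saccade", forced_abort_rate_lc = 0), seed = 5)
  expect_equal(sum(ev0$forced_abort), 0)

  n <- 10000L
  spec <- task_spec("saccade", n_trials_per_condition = n,
                    n_unpredictable_reward = 0L, n_unpredictable_airpuff = 0L,
                    forced_abort_rate_lc = 0.2, abort_rate_hc = 0)
  ev <- generate_session_events(spec, seed = 17)
  frac <- sum(ev$forced_abort) / n
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("invalid task specifications are rejected", {
  expect_error(task_spec("saccade", n_trials_per_condition = 0),
               "positive count")
  expect_error(task_spec("lever_press"))
  expect_error(task_spec("saccade", forced_abort_rate_lc = 1.2), "range")
  expect_error(task_spec("saccade", fixation_duration_hc = -5), "range")
})

test_that("event generation is deterministic given (spec, seed)", {
  a <- generate_session_events(task_spec("saccade"), seed = 99)
  b <- generate_session_events(task_spec("saccade"), seed = 99)
  expect_identical(a, b)
  c <- generate_session_events(task_spec("saccade"), seed = 100)
  expect_false(identical(a, c))
})
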