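test_that("softmax probabilities match direct evaluation and its limits", {
  expect_equal(choice_probabilities(c(0.5, 0.5), 1), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(1, 0), 0.5)[1], 1 / (1 + exp(-2)))
  expect_equal(choice_probabilities(c(1, 0), 1e6), c(0.5, 0.5),
               tolerance = 1e-5)
  # overflow safety and shift invariance
  expect_equal(choice_probabilities(c(1000, 999), 0.001),
               choice_probabilities(c(1, 0), 0.001))
  withr::with_seed(2, {
    for (i in 1:20) {
      v <- rnorm(2); beta <- runif(1, 0.01, 5); k <- rnorm(1, 0, 10)
      p <- choice_probabilities(v, beta)
      expect_equal(sum(p), 1)
      expect_true(all(p > 0))
      expect_equal(p, choice_probabilities(v + k, beta))
    }
  })
  expect_error(choice_probabilities(c(NA, 1), 1), "finite")
  expect_error(choice_probabilities(c(1, 0), 0), "range")
})

test_that("value updates follow the delta rule and its variants", {
  expect_equal(update_values(c(0.5, 0.5), 1, 1, 1)[1], 1)
  expect_equal(update_values(c(0.4, 0.7), 2, 1, 0), c(0.4, 0.7))
  expect_equal(update_values(c(0.2, 0.5), 1, 1, 0.5)[1], 0.6)
  # unchosen option handling per variant
  v <- c(0.6, 0.4)
  expect_equal(update_values(v, 1, 1, 0.5, "chosen_only")[2], 0.4)
  expect_equal(update_values(v, 1, 1, 0.5, "anticorrelated_full")[2],
               0.4 + 0.5 * (0 - 0.4))
  expect_equal(update_values(v, 1, 0, 0.5, "anticorrelated_full")[2],
               0.4 + 0.5 * (1 - 0.4))
  expect_equal(update_values(v, 1, 1, 0.5, "anticorrelated_decay")[2], 0.2)
  expect_error(update_values(v, 1, 0.5, 0.3), "0 or 1")
  # contraction: |V' - R| = (1 - alpha) |V - R|
  withr::with_seed(3, {
    for (i in 1:20) {
      v0 <- runif(1); alpha <- runif(1); r <- rbinom(1, 1, 0.5)
      v1 <- update_values(c(v0, 0), 1, r, alpha)[1]
      expect_equal(abs(v1 - r), (1 - alpha) * abs(v0 - r))
    }
  })
})

test_that("session log-likelihood matches a literal hand trace", {
  ses <- data.frame(cost_condition = c("HC", "HC", "LC", "HC", "LC"),
                    chosen = c(1L, 1L, 2L, 2L, 1L),
                    rewarded = c(1L, 1L, 0L, 0L, 1L))
  for (variant in c("chosen_only", "anticorrelated_full",
                    "anticorrelated_decay")) {
    p <- rl_params(0.4, 0.25, 0.3, 0.6, variant = variant)
    by_hand <- hand_rl_loglik(ses$chosen[ses$cost_condition == "HC"],
                              ses$rewarded[ses$cost_condition == "HC"],
                              0.4, 0.3, variant) +
               hand_rl_loglik(ses$chosen[ses$cost_condition == "LC"],
                              ses$rewarded[ses$cost_condition == "LC"],
                              0.25, 0.6, variant)
    expect_equal(session_log_likelihood(p, ses), by_hand, tolerance = 1e-12)
  }
})

test_that("zero learning rates give n * log(0.5) and relabeling is neutral", {
  p0 <- rl_params(0, 0, 0.7, 0.7)
  ses <- generate_exploration_choices(rl_params(0.3, 0.2, 0.2, 0.2),
                                      task_spec("exploration"), seed = 41)
  expect_equal(session_log_likelihood(p0, ses), nrow(ses) * log(0.5))
  # swapping the two stimulus labels leaves the likelihood unchanged
  p <- rl_params(0.3, 0.2, 0.2, 0.2)
  swapped <- ses
  swapped$chosen <- 3L - ses$chosen
  expect_equal(session_log_likelihood(p, ses),
               session_log_likelihood(p, swapped))
  expect_warning(ll0 <- session_log_likelihood(p, ses[0, ]), "empty")
  expect_equal(ll0, 0)
})

test_that("a deterministic single-choice session hits the beta bound, flagged", {
  ses <- data.frame(cost_condition = rep(c("HC", "LC"), each = 30),
                    chosen = 1L, rewarded = 1L)
  fit <- fit_rl(list(s1 = ses))
  expect_true(fit$fits$boundary_hc | fit$fits$boundary_lc)
})

test_that("the fitted optimum is never worse than the generating parameters", {
  p <- rl_params(0.3, 0.2, 0.2, 0.2)
  spec <- task_spec("exploration", n_trials_per_condition = 60L)
  for (i in 1:6) {
    ses <- generate_exploration_choices(p, spec, seed = 600 + i)
    fit <- fit_rl(list(s = ses))
    expect_gte(fit$fits$loglik, session_log_likelihood(p, ses) - 1e-6)
  }
})

test_that("pooled fitting recovers the generating parameters", {
  p <- rl_params(0.3, 0.2, 0.2, 0.2)
  es <- task_spec("exploration")
  ss <- lapply(1:40, function(i)
    generate_exploration_choices(p, es, seed = 1000 + i))
  names(ss) <- paste0("s", seq_along(ss))
  fit <- fit_rl(ss, mode = "pooled")
  expect_lt(abs(fit$fits$alpha_hc - 0.3), 0.15)
  expect_lt(abs(fit$fits$alpha_lc - 0.2), 0.15)
  expect_lt(abs(fit$fits$beta_hc - 0.2), 0.1)
  expect_lt(abs(fit$fits$beta_lc - 0.2), 0.1)
  expect_gt(fit$fits$log_alpha_ratio, 0)
})

test_that("parameter recovery reports are calibrated at the null", {
  rec <- parameter_recovery(rl_params(0.25, 0.25, 0.2, 0.2),
                            n_sessions = 24L, n_trials_per_condition = 80L,
                            seed = 9)
  expect_gt(rec$log_ratio$sign_recovery_rate, 0.2)
  expect_lt(rec$log_ratio$sign_recovery_rate, 0.8)
  expect_named(rec$bias, c("alpha_hc", "alpha_lc", "beta_hc", "beta_lc"))
  expect_true(all(is.finite(rec$rmse)))
})
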