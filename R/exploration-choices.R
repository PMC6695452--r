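#' Generate exploration-task choices from the RL model
#'
#' Simulates one exploration session: on each trial the two stimuli of the
#' trial's cost condition are offered, a choice is sampled from the softmax
#' of the current stimulus values, and the chosen value is updated by the
#' delta rule with the condition's learning rate. Reward is deterministic
#' given the choice: the R+ stimulus of the condition always pays, the R-
#' stimulus never does. Which of the two stimulus ids is R+ is randomized
#' per condition per session.
#'
#' @param true_params generating [rl_params()].
#' @param spec an exploration [task_spec()].
#' @param seed integer seed.
#' @param v0 initial stimulus value (default 0.5).
#' @return a `behavioral_session` data frame with columns `trial`,
#'   `cost_condition`, `stim_a`, `stim_b` (the presented pair), `chosen`
#'   (1 or 2), `rewarded`, `correct` (chose the R+ stimulus) and
#'   `p_chosen` (model probability of the sampled choice). Ground truth
#'   (`true_params`, R+ assignment, value trajectories) is attached as
#'   attributes for recovery testing, not used by the fitting code.
#' @export
generate_exploration_choices <- function(true_params, spec, seed = 1L,
                                         v0 = 0.5) {
  stop_if(!inherits(true_params, "rl_params"), "`true_params` must be rl_params")
  stop_if(!inherits(spec, "task_spec") || spec$task_kind != "exploration",
          "`spec` must be an exploration task_spec")
  with_local_seed(seed, {
    n <- spec$n_trials_per_condition
    cond <- sample(rep(c("HC", "LC"), each = n))
    n_tot <- length(cond)
    rplus <- c(HC = sample(1:2, 1), LC = sample(1:2, 1))
    v <- list(HC = c(v0, v0), LC = c(v0, v0))
    chosen <- integer(n_tot)
    rewarded <- integer(n_tot)
    p_chosen <- numeric(n_tot)
    v_trace <- matrix(NA_real_, n_tot, 2L)
    for (t in seq_len(n_tot)) {
      cc <- cond[t]
      alpha <- if (cc == "HC") true_params$alpha_hc else true_params$alpha_lc
      beta <- if (cc == "HC") true_params$beta_hc else true_params$beta_lc
      p <- choice_probabilities(v[[cc]], beta)
      ch <- if (runif(1) < p[1]) 1L else 2L
      r <- as.integer(ch == rplus[[cc]])
      chosen[t] <- ch
      rewarded[t] <- r
      p_chosen[t] <- p[ch]
      v_trace[t, ] <- v[[cc]]
      v[[cc]] <- update_values(v[[cc]], ch, r, alpha, true_params$variant)
    }
    ses <- data.frame(
      trial = seq_len(n_tot),
      cost_condition = cond,
      stim_a = 1L, stim_b = 2L,
      chosen = chosen,
      rewarded = rewarded,
      correct = as.integer(chosen == rplus[cond]),
      p_chosen = p_chosen,
      stringsAsFactors = FALSE
    )
    attr(ses, "true_params") <- true_params
    attr(ses, "rplus") <- rplus
    attr(ses, "value_trace") <- v_trace
    attr(ses, "seed") <- as.integer(seed)
    class(ses) <- c("behavioral_session", "data.frame")
    ses
  })
}
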