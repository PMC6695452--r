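# Independent oracles and small fixtures used across the test files.

derive_seed <- dopacost:::derive_seed

# auROC by exhaustive pair counting (ties count 1/2)
brute_auroc <- function(x, y) {
  gt <- outer(x, y, ">")
  eq <- outer(x, y, "==")
  mean(gt + 0.5 * eq)
}

# signed-rank p by literal enumeration over all 2^n sign assignments;
# ranks are tie-averaged ranks of |d| (zeros must be removed beforehand)
brute_signed_rank_p <- function(d, alternative = "two.sided") {
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_leq <- mean(w_all <= w_obs + 1e-12)
  p_geq <- mean(w_all >= w_obs - 1e-12)
  switch(alternative,
         two.sided = min(1, 2 * min(p_leq, p_geq)),
         greater = p_geq,
         less = p_leq)
}

# literal trial-by-trial R re-implementation of the RL choice likelihood
hand_rl_loglik <- function(chosen, rewarded, alpha, beta, variant = "chosen_only",
                           v0 = 0.5) {
  v <- c(v0, v0)
  ll <- 0
  for (t in seq_along(chosen)) {
    p <- exp(v / beta) / sum(exp(v / beta))
    ll <- ll + log(max(p[chosen[t]], 1e-12))
    c <- chosen[t]; o <- 3 - c; r <- rewarded[t]
    v[c] <- v[c] + alpha * (r - v[c])
    if (variant == "anticorrelated_full") v[o] <- v[o] + alpha * ((1 - r) - v[o])
    if (variant == "anticorrelated_decay") v[o] <- v[o] + alpha * (0 - v[o])
  }
  ll
}

# sessions of Bernoulli choices drawn straight from the learning curve
sim_curve_sessions <- function(n_ses, n_tr, a, b, seed) {
  withr::with_seed(seed, lapply(seq_len(n_ses), function(i)
    rbinom(n_tr, 1, learning_curve_value(a, b, seq_len(n_tr)))))
}

# a minimal one-trial event table (for generators that just need a span)
tiny_events <- function(t_end = 10) {
  ev <- generate_session_events(task_spec("saccade", n_trials_per_condition = 1L,
                                          n_unpredictable_reward = 0L,
                                          n_unpredictable_airpuff = 0L,
                                          abort_rate_hc = 0,
                                          forced_abort_rate_lc = 0), seed = 1)
  ev$t_trial_end[nrow(ev)] <- max(ev$t_trial_end, t_end)
  ev
}

# neuron_record from raw spike times (bypasses the generator)
fake_neuron <- function(spike_times, waveform = 350, id = "fake") {
  structure(list(neuron_id = id, spike_times = sort(spike_times),
                 waveform_duration_us = waveform, subtype = "value"),
            class = "neuron_record")
}
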