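#' Rescorla-Wagner / softmax model parameters
#'
#' The learning model maintains one value per stimulus and cost condition.
#' After each choice the chosen stimulus value moves toward the obtained
#' outcome, `V <- V + alpha * (R - V)` with the learning rate `alpha` of the
#' trial's cost condition (hard-bounded to \[0, 1\]). Choice between the two
#' stimuli of a trial follows a softmax on `V / beta`, where `beta > 0` sets
#' the amount of exploration (larger `beta`, more random choice).
#'
#' Variants for the unchosen stimulus:
#' \describe{
#'   \item{`chosen_only`}{standard delta rule; unchosen value untouched.}
#'   \item{`anticorrelated_full`}{unchosen value moves toward `1 - R` with
#'     the same learning rate (the animal assumes the two cues have
#'     anticorrelated outcomes).}
#'   \item{`anticorrelated_decay`}{unchosen value decays toward 0 with the
#'     same learning rate.}
#' }
#' The two anticorrelated forms are interpretations of "the unchosen option
#' is updated alongside the chosen one", shipped as labelled alternatives.
#'
#' @param alpha_hc,alpha_lc learning rates in \[0, 1\] for the high- and
#'   low-cost condition.
#' @param beta_hc,beta_lc exploration scales, strictly positive.
#' @param variant update rule for the unchosen option.
#' @return an `rl_params` list.
#' @export
rl_params <- function(alpha_hc, alpha_lc, beta_hc, beta_lc,
                      variant = c("chosen_only", "anticorrelated_full",
                                  "anticorrelated_decay")) {
  variant <- match.arg(variant)
  check_number(alpha_hc, "alpha_hc", 0, 1)
  check_number(alpha_lc, "alpha_lc", 0, 1)
  check_number(beta_hc, "beta_hc", 0, strict_lower = TRUE)
  check_number(beta_lc, "beta_lc", 0, strict_lower = TRUE)
  structure(list(alpha_hc = alpha_hc, alpha_lc = alpha_lc,
                 beta_hc = beta_hc, beta_lc = beta_lc, variant = variant),
            class = "rl_params")
}

variant_code <- function(variant) {
  match(variant, c("chosen_only", "anticorrelated_full", "anticorrelated_decay"))
}

#' Softmax choice probabilities over two stimulus values
#'
#' `P_j = exp(V_j / beta) / sum_i exp(V_i / beta)`, computed with
#' max-subtraction so extreme `V / beta` cannot overflow.
#'
#' @param v numeric vector of 2 stimulus values.
#' @param beta exploration scale (> 0).
#' @return probabilities of length 2, summing to 1.
#' @export
choice_probabilities <- function(v, beta) {
  stop_if(length(v) != 2L || !all(is.finite(v)), "`v` must be 2 finite values")
  check_number(beta, "beta", 0, strict_lower = TRUE)
  z <- v / beta
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Delta-rule value update for one trial
#'
#' @param v numeric vector of 2 stimulus values (one cost condition).
#' @param chosen index (1 or 2) of the chosen stimulus.
#' @param r outcome, 0 or 1.
#' @param alpha learning rate for this trial's cost condition.
#' @param variant unchosen-option rule, see [rl_params()].
#' @return updated value vector.
#' @export
update_values <- function(v, chosen, r,
                          alpha, variant = "chosen_only") {
  stop_if(!(chosen %in% c(1L, 2L)), "`chosen` must be 1 or 2")
  stop_if(!(r %in% c(0, 1)), "`r` must be 0 or 1")
  check_number(alpha, "alpha", 0, 1)
  other <- 3L - chosen
  v[chosen] <- v[chosen] + alpha * (r - v[chosen])
  if (variant == "anticorrelated_full") {
    v[other] <- v[other] + alpha * ((1 - r) - v[other])
  } else if (variant == "anticorrelated_decay") {
    v[other] <- v[other] + alpha * (0 - v[other])
  }
  v
}

#' Log-likelihood of one session's choices under the RL model
#'
#' Forward pass in trial order, with independent value states per cost
#' condition initialized at `V = 0.5`. The log probability of each observed
#' choice is accumulated before the value update for that trial.
#' Probabilities are floored at 1e-12 inside the log.
#'
#' @param params an [rl_params()] object.
#' @param session a behavioural session data frame with columns
#'   `cost_condition` ("HC"/"LC"), `chosen` (1 or 2) and `rewarded` (0/1),
#'   in trial order. Rows with missing choices (aborts) are skipped.
#' @param v0 initial stimulus value (default 0.5, chance level).
#' @return the summed log-likelihood (0 for an empty session, with warning).
#' @export
session_log_likelihood <- function(params, session, v0 = 0.5) {
  stop_if(!inherits(params, "rl_params"), "`params` must be rl_params")
  ses <- session[!is.na(session$chosen), , drop = FALSE]
  if (nrow(ses) == 0L) {
    warning("empty session: log-likelihood 0")
    return(0)
  }
  ll <- 0
  for (cc in c("HC", "LC")) {
    rows <- ses$cost_condition == cc
    if (!any(rows)) next
    alpha <- if (cc == "HC") params$alpha_hc else params$alpha_lc
    beta <- if (cc == "HC") params$beta_hc else params$beta_lc
    ll <- ll + rl_loglik_cpp(as.integer(ses$chosen[rows]),
                             as.numeric(ses$rewarded[rows]),
                             alpha, beta, variant_code(params$variant), v0)
  }
  ll
}

# single-condition negative log-likelihood; `chosen`/`rewarded` are lists
# with one element per session so the value state resets between sessions
condition_negll <- function(par, chosen, rewarded, variant_id, v0) {
  -sum(mapply(function(ch, rw)
    rl_loglik_cpp(ch, rw, par[1], par[2], variant_id, v0),
    chosen, rewarded))
}

fit_condition <- function(chosen, rewarded, variant_id, v0,
                          n_starts = 16L, beta_bounds = c(1e-3, 10)) {
  if (!is.list(chosen)) {
    chosen <- list(chosen)
    rewarded <- list(rewarded)
  }
  starts <- as.matrix(expand.grid(alpha = c(0.05, 0.2, 0.5, 0.9),
                                  beta = c(0.05, 0.2, 1, 5)))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], condition_negll, method = "L-BFGS-B",
            lower = c(1e-6, beta_bounds[1]), upper = c(1, beta_bounds[2]),
            control = list(factr = 1e6),
            chosen = chosen, rewarded = rewarded,
            variant_id = variant_id, v0 = v0),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(alpha = NA_real_, beta = NA_real_, loglik = NA_real_,
                converged = FALSE, boundary = NA))
  }
  tol <- 1e-6
  list(alpha = unname(best$par[1]), beta = unname(best$par[2]),
       loglik = -best$value, converged = n_ok > 0L,
       boundary = best$par[2] <= beta_bounds[1] + tol ||
         best$par[2] >= beta_bounds[2] - tol ||
         best$par[1] >= 1 - tol)
}

#' Fit the RL model to behavioural sessions by maximum likelihood
#'
#' Per-session fitting is the primary mode: each session gets its own
#' `(alpha_HC, alpha_LC, beta_HC, beta_LC)` and across-session inference is
#' run on the per-session `log(alpha_HC / alpha_LC)`. Because the two cost
#' conditions have independent value states and (by default) independent
#' parameters, the likelihood factorizes and each condition is maximized
#' separately with bounded multi-start L-BFGS-B (`alpha` in \[0, 1\], `beta`
#' in \[1e-3, 10\], 16 starts). With `beta_mode = "shared"` a common `beta`
#' is profiled over a joint 3-parameter search.
#'
#' @param sessions a data frame with columns `session_id`, `trial`,
#'   `cost_condition`, `chosen`, `rewarded` (as produced by
#'   [generate_exploration_choices()] rows bound together), or a list of
#'   per-session data frames.
#' @param variant unchosen-option update rule, see [rl_params()].
#' @param mode `"per_session"` (default) or `"pooled"` (one parameter set
#'   for all sessions).
#' @param beta_mode `"per_condition"` (default) or `"shared"`.
#' @param v0 initial stimulus value.
#' @param n_starts number of optimizer starts.
#' @return an `rl_fit` object: `$fits` (one row per fitted unit with
#'   parameter estimates, log-likelihood, convergence and boundary flags,
#'   and `log_alpha_ratio`), plus `$variant`, `$mode`.
#' @export
fit_rl <- function(sessions, variant = c("chosen_only", "anticorrelated_full",
                                         "anticorrelated_decay"),
                   mode = c("per_session", "pooled"),
                   beta_mode = c("per_condition", "shared"),
                   v0 = 0.5, n_starts = 16L) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  beta_mode <- match.arg(beta_mode)
  if (is.data.frame(sessions)) {
    stop_if(is.null(sessions$session_id), "`sessions` needs a session_id column")
    sessions <- split(sessions, sessions$session_id)
  }
  stop_if(length(sessions) == 0L, "no sessions supplied")
  vid <- variant_code(variant)

  fit_unit <- function(dfs, id) {
    dfs <- lapply(dfs, function(df) df[!is.na(df$chosen), , drop = FALSE])
    out <- list(session_id = id)
    for (cc in c("HC", "LC")) {
      ch <- lapply(dfs, function(df)
        as.integer(df$chosen[df$cost_condition == cc]))
      rw <- lapply(dfs, function(df)
        as.numeric(df$rewarded[df$cost_condition == cc]))
      stop_if(sum(lengths(ch)) == 0L,
              sprintf("unit %s has no %s trials", id, cc))
      f <- fit_condition(ch, rw, vid, v0, n_starts = n_starts)
      suff <- tolower(cc)
      out[[paste0("alpha_", suff)]] <- f$alpha
      out[[paste0("beta_", suff)]] <- f$beta
      out[[paste0("loglik_", suff)]] <- f$loglik
      out[[paste0("converged_", suff)]] <- f$converged
      out[[paste0("boundary_", suff)]] <- f$boundary
    }
    out$loglik <- out$loglik_hc + out$loglik_lc
    out$log_alpha_ratio <- log(out$alpha_hc / out$alpha_lc)
    out$log_beta_ratio <- log(out$beta_hc / out$beta_lc)
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  if (mode == "pooled") {
    fits <- fit_unit(sessions, "pooled")
  } else {
    ids <- names(sessions)
    if (is.null(ids)) ids <- as.character(seq_along(sessions))
    fits <- do.call(rbind, Map(function(df, id) fit_unit(list(df), id),
                               sessions, ids))
    rownames(fits) <- NULL
  }
  if (beta_mode == "shared") {
    # profile a common beta: refit both conditions on a shared beta grid
    fits <- refit_shared_beta(sessions, fits, vid, v0, mode)
  }
  if (any(!fits$converged_hc | !fits$converged_lc)) {
    warning("some sessions failed to converge on every start; flagged in $fits")
  }
  structure(list(fits = fits, variant = variant, mode = mode,
                 beta_mode = beta_mode, v0 = v0),
            class = "rl_fit")
}

refit_shared_beta <- function(sessions, fits, vid, v0, mode) {
  units <- if (mode == "pooled") {
    list(pooled = do.call(rbind, lapply(sessions, function(df)
      df[, c("cost_condition", "chosen", "rewarded")])))
  } else sessions
  for (i in seq_along(units)) {
    df <- units[[i]][!is.na(units[[i]]$chosen), , drop = FALSE]
    negll <- function(par) {
      ll <- 0
      for (cc in c("HC", "LC")) {
        rows <- df$cost_condition == cc
        a <- if (cc == "HC") par[1] else par[2]
        ll <- ll + rl_loglik_cpp(as.integer(df$chosen[rows]),
                                 as.numeric(df$rewarded[rows]),
                                 a, par[3], vid, v0)
      }
      -ll
    }
    best <- NULL
    for (b0 in c(0.05, 0.2, 1, 5)) for (a0 in c(0.1, 0.5)) {
      fit <- tryCatch(optim(c(a0, a0, b0), negll, method = "L-BFGS-B",
                            lower = c(1e-6, 1e-6, 1e-3), upper = c(1, 1, 10),
                            control = list(factr = 1e6)),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (!is.null(best)) {
      fits$alpha_hc[i] <- best$par[1]; fits$alpha_lc[i] <- best$par[2]
      fits$beta_hc[i] <- fits$beta_lc[i] <- best$par[3]
      fits$loglik[i] <- -best$value
      fits$log_alpha_ratio[i] <- log(best$par[1] / best$par[2])
      fits$log_beta_ratio[i] <- 0
    }
  }
  fits
}

#' Closed-loop parameter recovery for the RL model
#'
#' Generates exploration sessions from known parameters, refits each
#' session, and summarizes estimation quality: per-parameter bias and RMSE,
#' the distribution of per-session `log(alpha_HC / alpha_LC)`, the rate at
#' which its sign matches the generating ratio, and one-sample tests of the
#' log-ratio against zero.
#'
#' @param true_params an [rl_params()] object used generatively.
#' @param n_sessions number of sessions in the cohort.
#' @param n_trials_per_condition trials per cost condition per session.
#' @param seed master seed.
#' @param variant fitting variant (defaults to the generating variant).
#' @return a list with `$fits`, `$bias`, `$rmse`, `$log_ratio`
#'   (values, mean, sign-recovery rate, t and signed-rank p), `$n_failed`.
#' @export
parameter_recovery <- function(true_params, n_sessions = 86L,
                               n_trials_per_condition = 100L, seed = 1L,
                               variant = NULL) {
  stop_if(!inherits(true_params, "rl_params"), "`true_params` must be rl_params")
  if (is.null(variant)) variant <- true_params$variant
  spec <- task_spec("exploration",
                    n_trials_per_condition = n_trials_per_condition)
  sessions <- lapply(seq_len(n_sessions), function(i) {
    generate_exploration_choices(true_params, spec,
                                 seed = derive_seed(seed, i))
  })
  names(sessions) <- sprintf("s%03d", seq_len(n_sessions))
  fit <- fit_rl(sessions, variant = variant)
  f <- fit$fits
  ok <- f$converged_hc & f$converged_lc & is.finite(f$log_alpha_ratio)
  truth <- c(alpha_hc = true_params$alpha_hc, alpha_lc = true_params$alpha_lc,
             beta_hc = true_params$beta_hc, beta_lc = true_params$beta_lc)
  est <- f[ok, names(truth), drop = FALSE]
  bias <- colMeans(est) - truth
  rmse <- sqrt(colMeans((t(t(as.matrix(est)) - truth))^2))
  lr <- f$log_alpha_ratio[ok]
  true_lr <- log(true_params$alpha_hc / true_params$alpha_lc)
  sign_rate <- if (true_lr == 0) mean(lr > 0) else mean(sign(lr) == sign(true_lr))
  tt <- t_test_summary(lr)
  wt <- wilcoxon_signed_rank(lr)
  list(fits = f, bias = bias, rmse = rmse,
       log_ratio = list(values = lr, mean = mean(lr), true = true_lr,
                        sign_recovery_rate = sign_rate,
                        p_t = tt$p_value, p_wilcoxon = wt$p_value),
       n_failed = sum(!ok))
}
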