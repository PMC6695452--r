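#' Cumulative-exponential learning curve
#'
#' Proportion of correct choices as a function of trial number:
#' `P(t) = 1/2 + (1/2 - 1/2 * exp(-a * t)) * b`, rising from chance (0.5)
#' with steepness `a` (per trial) to a plateau at `0.5 + b/2`.
#'
#' @param a steepness, > 0.
#' @param b plateau scale in (0, 1].
#' @param t trial index (vectorized), >= 0. The first choice trial of a
#'   condition is `t = 1`.
#' @return probabilities in \[0.5, 0.5 + b/2\].
#' @export
learning_curve_value <- function(a, b, t) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0, upper = 1, strict_lower = TRUE)
  stop_if(any(t < 0), "`t` must be >= 0")
  0.5 + (0.5 - 0.5 * exp(-a * t)) * b
}

# Bernoulli/binomial negative log-likelihood of (k successes out of n) per
# trial index; probabilities clipped inside the logs.
curve_negll <- function(par, t, k, n, clip = 1e-6) {
  p <- 0.5 + (0.5 - 0.5 * exp(-par[1] * t)) * par[2]
  p <- pmin(pmax(p, clip), 1 - clip)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

curve_starts <- function() {
  as.matrix(expand.grid(a = c(0.02, 0.08, 0.3, 1.2), b = c(0.5, 0.95)))
}

#' Fit the learning curve by maximum likelihood
#'
#' Treats each choice as an independent Bernoulli draw with success
#' probability `P(t)` and maximizes the likelihood over `(a, b)` with
#' bounded multi-start optimization (`a` in (0, 10\], `b` in (0, 1\], 8
#' starts, L-BFGS-B). Accepts a single session (0/1 vector) or pooled data
#' given as per-trial success counts.
#'
#' @param correct 0/1 vector of per-trial outcomes, or per-trial success
#'   counts when `n_obs` is given.
#' @param trial trial indices (default `1:length(correct)`).
#' @param n_obs number of observations per trial index (default 1; use the
#'   per-index session count for pooled fits).
#' @param n_starts number of optimizer starts (default 8).
#' @return a `learning_curve_fit` list: `a`, `b`, `loglik`, `converged`,
#'   `boundary` (TRUE when a parameter sits on its bound), `n_trials`.
#' @export
fit_learning_curve <- function(correct, trial = seq_along(correct),
                               n_obs = rep(1, length(correct)),
                               n_starts = 8L) {
  stop_if(length(correct) != length(trial) || length(correct) != length(n_obs),
          "`correct`, `trial`, `n_obs` must have equal length")
  stop_if(any(correct < 0 | correct > n_obs),
          "`correct` must lie in [0, n_obs] per trial")
  stop_if(sum(n_obs) < 10, "need at least 10 observations to fit")
  bounds_lo <- c(1e-4, 1e-4)
  bounds_hi <- c(10, 1)
  starts <- curve_starts()[seq_len(min(n_starts, 8L)), , drop = FALSE]
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], curve_negll, method = "L-BFGS-B",
            lower = bounds_lo, upper = bounds_hi,
            control = list(factr = 1e6),
            t = trial, k = correct, n = n_obs),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  stop_if(is.null(best), "learning-curve fit failed on every start")
  tol <- 1e-6
  structure(list(
    a = unname(best$par[1]), b = unname(best$par[2]),
    loglik = -best$value, converged = n_ok > 0L,
    boundary = any(best$par <= bounds_lo + tol) ||
      any(best$par >= bounds_hi - tol),
    n_trials = sum(n_obs), n_starts_ok = n_ok
  ), class = "learning_curve_fit")
}

pool_sessions <- function(sessions) {
  len <- max(vapply(sessions, length, integer(1)))
  k <- n <- numeric(len)
  for (s in sessions) {
    idx <- seq_along(s)
    k[idx] <- k[idx] + s
    n[idx] <- n[idx] + 1
  }
  list(trial = seq_len(len), k = k, n = n)
}

#' Bootstrap confidence intervals for the pooled learning-curve fit
#'
#' Resamples whole sessions with replacement (session-level inference),
#' refits the pooled curve on each replicate, and returns percentile
#' intervals for `a` and `b`. Replicates whose refit fails are dropped and
#' counted.
#'
#' @param sessions list of 0/1 per-trial vectors (>= 2 sessions).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param n_starts optimizer starts per refit (a light 2-start search; the
#'   pooled likelihood is well-behaved under resampling).
#' @return list with `ci_a`, `ci_b` (length-2 vectors), `estimate` (the
#'   full-data fit), `boot` (replicate estimates), `n_failed`.
#' @export
bootstrap_curve_ci <- function(sessions, n_boot = 1000L, seed = 1L,
                               level = 0.95, n_starts = 2L) {
  stop_if(length(sessions) < 2L, "need >= 2 sessions to bootstrap")
  stop_if(n_boot < 100L, "`n_boot` must be >= 100")
  pooled <- pool_sessions(sessions)
  est <- fit_learning_curve(pooled$k, pooled$trial, pooled$n)
  boot <- with_local_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2L, dimnames = list(NULL, c("a", "b")))
    for (r in seq_len(n_boot)) {
      idx <- sample(length(sessions), replace = TRUE)
      p <- pool_sessions(sessions[idx])
      f <- tryCatch(fit_learning_curve(p$k, p$trial, p$n, n_starts = n_starts),
                    error = function(e) NULL)
      if (!is.null(f)) out[r, ] <- c(f$a, f$b)
    }
    out
  })
  ok <- complete.cases(boot)
  alpha <- (1 - level) / 2
  list(
    ci_a = unname(quantile(boot[ok, "a"], c(alpha, 1 - alpha))),
    ci_b = unname(quantile(boot[ok, "b"], c(alpha, 1 - alpha))),
    estimate = est,
    boot = boot[ok, , drop = FALSE],
    n_failed = sum(!ok)
  )
}

#' Smoothed across-session learning process
#'
#' Mean proportion correct per trial index across sessions, then a
#' centered moving average. Edges use the available (shorter) window.
#'
#' @param sessions list of 0/1 per-trial vectors.
#' @param window odd window length (>= 1); 1 returns the raw proportions.
#' @return numeric vector of smoothed proportions, one per trial index.
#' @export
smoothed_learning_process <- function(sessions, window = 5L) {
  window <- as.integer(window)
  stop_if(window < 1L || window %% 2L == 0L, "`window` must be odd and >= 1")
  pooled <- pool_sessions(sessions)
  prop <- pooled$k / pooled$n
  stop_if(window > length(prop), "`window` exceeds the series length")
  if (window == 1L) return(prop)
  half <- window %/% 2L
  vapply(seq_along(prop), function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(prop), i + half)
    mean(prop[lo:hi])
  }, numeric(1))
}
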