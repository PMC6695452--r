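#' Wilcoxon signed-rank test with exact small-sample enumeration
#'
#' One-sample (or paired, via `y`) signed-rank test. Zero differences are
#' dropped before ranking (with their count reported); absolute values are
#' ranked with average ranks for ties. For `n <= exact_max` (default 12)
#' the null distribution of the positive-rank sum is computed by exact
#' enumeration over all 2^n sign assignments (valid with ties, since the
#' observed tie pattern is conditioned on); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x numeric values (or first member of pairs).
#' @param y optional second member of pairs; the test is on `x - y`.
#' @param mu null location (default 0).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_max largest n for exact enumeration.
#' @return list with `statistic` (positive-rank sum W), `p_value`, `n`
#'   (after zero removal), `zeros_dropped`, `method`. When every
#'   difference is zero the test is undefined: `p_value` is `NA` and
#'   `degenerate` is set.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max = 12L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x - mu else (x - y) - mu
  stop_if(any(!is.finite(d)), "differences must be finite")
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                zeros_dropped = zeros, degenerate = TRUE,
                method = "undefined (all differences zero)"))
  }
  if (n < 5L) {
    warning("fewer than 5 non-zero differences; the test has little power")
  }
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: enumerate the 2^n sign assignments via a generating
    # function over doubled ranks (integers even with .5 average ranks)
    dr <- as.integer(round(2 * r))
    total <- sum(dr)
    dist <- numeric(total + 1L)
    dist[1L] <- 1
    for (v in dr) {
      shifted <- c(numeric(v), dist[seq_len(total + 1L - v)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_leq <- sum(dist[seq_len(w2 + 1L)])
    p_geq <- sum(dist[(w2 + 1L):(total + 1L)])
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_leq, p_geq)),
      greater = p_geq,
      less = p_leq)
    method <- "exact enumeration"
  } else {
    mu_w <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_raw <- w - mu_w
    cc <- switch(alternative,
      two.sided = sign(z_raw) * 0.5, greater = 0.5, less = -0.5)
    z <- (z_raw - cc) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z))
    p <- min(1, p)
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p_value = p, n = n, zeros_dropped = zeros,
       degenerate = FALSE, method = method)
}

#' One-sample or paired t test summary
#'
#' Thin wrapper around [stats::t.test()] returning a flat summary. A
#' zero-variance sample is degenerate: if its mean already equals `mu` the
#' conventional `t = 0, p = 1` is returned (flagged); otherwise the test
#' is undefined and an error is signalled.
#'
#' @param x numeric values (or first member of pairs).
#' @param y optional second member of pairs (paired test on `x - y`).
#' @param mu null mean (default 0).
#' @return list with `t`, `df`, `p_value`, `mean`, `n`, `degenerate`.
#' @export
t_test_summary <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x else x - y
  stop_if(length(d) < 2L, "need at least 2 observations")
  stop_if(any(!is.finite(d)), "values must be finite")
  if (sd(d) == 0) {
    if (mean(d) == mu) {
      return(list(t = 0, df = length(d) - 1L, p_value = 1,
                  mean = mean(d), n = length(d), degenerate = TRUE))
    }
    stop("zero variance with mean != mu: t test undefined", call. = FALSE)
  }
  tt <- t.test(d, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean = mean(d), n = length(d),
       degenerate = FALSE)
}

#' Session-wise log-ratio statistic between cost conditions
#'
#' For a positive parameter estimated per session in both cost conditions,
#' computes `log(theta_HC / theta_LC)` per session and tests its mean
#' against zero with both a two-tailed t test (primary) and the signed-rank
#' test. Sessions with a non-positive parameter in either condition are
#' excluded and counted.
#'
#' @param param_hc,param_lc per-session parameter estimates.
#' @return a `log_ratio_result` list: `values`, `mean`, `n`,
#'   `n_excluded`, `t`, `df`, `p_t`, `p_wilcoxon`.
#' @export
log_ratio_stat <- function(param_hc, param_lc) {
  stop_if(length(param_hc) != length(param_lc),
          "parameter vectors must have equal length")
  ok <- is.finite(param_hc) & is.finite(param_lc) &
    param_hc > 0 & param_lc > 0
  lr <- log(param_hc[ok] / param_lc[ok])
  stop_if(length(lr) < 2L, "fewer than 2 usable sessions")
  tt <- tryCatch(t_test_summary(lr), error = function(e)
    list(t = NA_real_, df = NA_real_, p_value = NA_real_))
  wt <- if (all(lr == 0)) list(p_value = NA_real_)
        else suppressWarnings(wilcoxon_signed_rank(lr))
  structure(list(values = lr, mean = mean(lr), n = length(lr),
                 n_excluded = sum(!ok),
                 t = tt$t, df = tt$df, p_t = tt$p_value,
                 p_wilcoxon = wt$p_value),
            class = "log_ratio_result")
}

#' Trial-by-trial Pearson correlation
#'
#' Used for control analyses relating per-trial behavioural measures
#' (fixation durations, RTs) to per-trial neural responses.
#'
#' @param x,y numeric vectors of equal length (>= 3, finite).
#' @return list with `r`, `p_value`, `n`.
#' @export
trialwise_correlation <- function(x, y) {
  stop_if(length(x) != length(y), "`x` and `y` must have equal length")
  stop_if(length(x) < 3L, "need at least 3 pairs")
  stop_if(any(!is.finite(x)) || any(!is.finite(y)), "values must be finite")
  stop_if(sd(x) == 0 || sd(y) == 0,
          "zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
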