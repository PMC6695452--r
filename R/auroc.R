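#' auROC contrast between high- and low-cost responses
#'
#' The area under the ROC curve for discriminating the two trial groups,
#' computed via the rank-sum (Mann-Whitney) identity: the probability that
#' a randomly drawn high-cost-trial response exceeds a randomly drawn
#' low-cost-trial response, with ties counting 1/2. Values above 0.5 mean
#' a larger response in the high-cost condition; below 0.5, smaller.
#'
#' @param responses_hc,responses_lc numeric response vectors (non-empty).
#' @return an `auroc_result` list: `auroc`, `n_hc`, `n_lc`, `low_n` (flag
#'   set when either group has fewer than 2 trials).
#' @export
auroc_condition_contrast <- function(responses_hc, responses_lc) {
  stop_if(length(responses_hc) == 0L || length(responses_lc) == 0L,
          "both response groups must be non-empty")
  stop_if(!all(is.finite(responses_hc)) || !all(is.finite(responses_lc)),
          "responses must be finite")
  n1 <- length(responses_hc)
  n2 <- length(responses_lc)
  r <- rank(c(responses_hc, responses_lc), ties.method = "average")
  auroc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  structure(list(auroc = auroc, n_hc = n1, n_lc = n2,
                 low_n = n1 < 2L || n2 < 2L),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("<auroc_result> auROC = %.3f (n HC = %d, n LC = %d)%s\n",
              x$auroc, x$n_hc, x$n_lc,
              if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' Population summary of per-neuron auROC values
#'
#' Median auROC across neurons plus a two-tailed signed-rank test of the
#' distribution against 0.5 (the signed-rank test is used throughout this
#' pipeline to limit the influence of outliers in small neuron samples).
#'
#' @param aurocs numeric vector of per-neuron auROC values, or a list of
#'   `auroc_result` objects; at least 5 neurons.
#' @return list with `median`, `p_value`, `n` and `note` (set when every
#'   auROC equals 0.5 exactly, where the test is undefined).
#' @export
population_auroc_summary <- function(aurocs) {
  if (is.list(aurocs)) {
    aurocs <- vapply(aurocs, function(a) a$auroc, numeric(1))
  }
  stop_if(length(aurocs) < 5L, "need >= 5 neurons for a population summary")
  if (all(aurocs == 0.5)) {
    return(list(median = 0.5, p_value = NA_real_, n = length(aurocs),
                note = "all auROC values are exactly 0.5; test undefined"))
  }
  test <- wilcoxon_signed_rank(aurocs, mu = 0.5)
  list(median = median(aurocs), p_value = test$p_value,
       statistic = test$statistic, n = length(aurocs), note = NULL)
}
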