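test_that("exact signed-rank p matches brute-force enumeration (with ties)", {
  withr::with_seed(7, {
    for (r in 1:30) {
      n <- sample(5:10, 1)
      d <- sample(c(-4:-1, 1:4), n, replace = TRUE) + 0.5 * rbinom(n, 1, 0.5)
      for (alt in c("two.sided", "greater", "less")) {
        mine <- wilcoxon_signed_rank(d, alternative = alt)
        expect_equal(mine$p_value, brute_signed_rank_p(d, alt),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("exact signed-rank agrees with the reference implementation", {
  # tie-free data, where stats::wilcox.test is also exact
  withr::with_seed(8, {
    for (r in 1:20) {
      n <- sample(6:12, 1)
      d <- round(rnorm(n, 0.3, 1), 6)
      ref <- wilcox.test(d, mu = 0, exact = TRUE)
      mine <- wilcoxon_signed_rank(d)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("large-sample signed-rank matches the corrected normal reference", {
  withr::with_seed(9, {
    d <- round(rnorm(40, 0.2, 1), 1)  # rounding forces ties
    mine <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(wilcox.test(d, mu = 0, exact = FALSE,
                                        correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("signed-rank handles zeros, shifts and degenerate input", {
  res <- wilcoxon_signed_rank(c(0, 0, 1, -2, 3, 4, 5, 0))
  expect_equal(res$zeros_dropped, 3)
  expect_equal(res$n, 5)
  big <- wilcoxon_signed_rank(rnorm(20) + 10)
  expect_lt(big$p_value, 0.01)
  degen <- wilcoxon_signed_rank(rep(0, 6))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_value))
})

test_that("t summaries match closed-form arithmetic", {
  ident <- t_test_summary(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  tri <- t_test_summary(c(1, 2, 3))
  expect_equal(tri$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tri$df, 2)
  expect_equal(tri$p_value, 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(t_test_summary(c(3, 3, 3)), "undefined")
  expect_error(t_test_summary(5), "at least 2")
})

test_that("t test type-I error is close to nominal under the null", {
  withr::with_seed(10, {
    rej <- replicate(1000, t_test_summary(rnorm(20))$p_value < 0.05)
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("log-ratio statistics handle exact and degenerate ratios", {
  lr0 <- log_ratio_stat(c(1, 2, 3), c(1, 2, 3))
  expect_equal(lr0$mean, 0)
  lr <- log_ratio_stat(1.5 * c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(lr$mean, log(1.5))
  expect_equal(lr$n, 4)
  mixed <- log_ratio_stat(c(2, -1, 3, 4, 5), c(1, 1, 1, 2, 2))
  expect_equal(mixed$n_excluded, 1)
  expect_equal(mixed$n, 4)
})

test_that("log-ratio inference recovers a true ratio across noisy sessions", {
  withr::with_seed(11, {
    lc <- exp(rnorm(40, 0, 0.3))
    hc <- 1.5 * lc * exp(rnorm(40, 0, 0.3))
  })
  lr <- log_ratio_stat(hc, lc)
  expect_lt(lr$p_t, 0.05)
  expect_lt(lr$p_wilcoxon, 0.05)
  expect_gt(lr$mean, 0)
})

test_that("trialwise correlation behaves on exact and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(trialwise_correlation(x, x)$r, 1)
  expect_lt(trialwise_correlation(x, -x + rnorm(5, 0, 1e-3))$r, 0)
  expect_error(trialwise_correlation(x, rep(1, 5)), "zero variance")
  expect_error(trialwise_correlation(x[1:2], x[1:2]), "at least 3")
  # invariant to reordering the pairs
  withr::with_seed(12, {
    a <- rnorm(30); b <- a + rnorm(30)
    idx <- sample(30)
  })
  expect_equal(trialwise_correlation(a, b)$r,
               trialwise_correlation(a[idx], b[idx])$r)
})
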