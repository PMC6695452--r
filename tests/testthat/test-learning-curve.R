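test_that("curve values match the closed form and its limits", {
  expect_equal(learning_curve_value(0.3, 0.8, 0), 0.5)
  expect_equal(learning_curve_value(0.1, 0.8, 10),
               0.5 + 0.5 * (1 - exp(-1)) * 0.8)
  expect_equal(learning_curve_value(50, 1, 1000), 1, tolerance = 1e-12)
  expect_error(learning_curve_value(0, 0.8, 1), "range")
  expect_error(learning_curve_value(0.1, 1.2, 1), "range")
})

test_that("the curve is non-decreasing and bounded by its plateau", {
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- runif(1, 0.01, 2); b <- runif(1, 0.05, 1)
      p <- learning_curve_value(a, b, 0:200)
      expect_true(all(diff(p) >= 0))
      expect_true(all(p >= 0.5 & p <= 0.5 + b / 2 + 1e-12))
    }
  })
})

test_that("fit likelihood at the optimum is at least that of the truth", {
  for (r in 1:8) {
    ds <- sim_curve_sessions(1, 120, 0.12, 0.85, seed = 50 + r)[[1]]
    f <- fit_learning_curve(ds)
    ll_truth <- -dopacost:::curve_negll(c(0.12, 0.85), seq_along(ds), ds,
                                        rep(1, length(ds)))
    expect_gte(f$loglik, ll_truth - 1e-6)
  }
})

test_that("all-correct data drives the plateau to its upper bound, flagged", {
  f <- fit_learning_curve(rep(1L, 50))
  expect_equal(f$b, 1, tolerance = 1e-4)
  expect_true(f$boundary)
})

test_that("destroying the time structure drives the fit to a boundary", {
  # a shuffled learning series is flat; the ML curve then jumps straight
  # to the plateau, pushing the steepness to its upper bound
  ds <- sim_curve_sessions(100, 100, 0.15, 0.9, seed = 77)
  pooled_shuffled <- withr::with_seed(78, lapply(ds, sample))
  f <- fit_learning_curve_pooled(pooled_shuffled)
  expect_true(f$boundary)
  expect_gt(f$a, 5)
})

test_that("smoothing is an identity at window 1 and flattens complements", {
  const <- list(rep(1L, 20), rep(1L, 20))
  expect_equal(smoothed_learning_process(const, 5), rep(1, 20))
  alt <- list(rep(c(0L, 1L), 10), rep(c(1L, 0L), 10))
  expect_equal(smoothed_learning_process(alt, 3), rep(0.5, 20))
  raw <- smoothed_learning_process(list(c(0, 1, 1, 0, 1)), 1)
  expect_equal(raw, c(0, 1, 1, 0, 1))
  expect_error(smoothed_learning_process(const, 4), "odd")
  expect_error(smoothed_learning_process(list(c(0, 1)), 5), "length")
})

test_that("bootstrap CIs collapse for identical sessions and are reproducible", {
  ses <- rep(list(c(rep(0L, 5), rep(1L, 45))), 10)
  ci <- bootstrap_curve_ci(ses, n_boot = 100, seed = 5)
  expect_equal(diff(ci$ci_a), 0, tolerance = 1e-6)
  expect_equal(diff(ci$ci_b), 0, tolerance = 1e-6)
  ds <- sim_curve_sessions(8, 60, 0.2, 0.8, seed = 91)
  c1 <- bootstrap_curve_ci(ds, n_boot = 100, seed = 7)
  c2 <- bootstrap_curve_ci(ds, n_boot = 100, seed = 7)
  expect_identical(c1$ci_a, c2$ci_a)
  expect_error(bootstrap_curve_ci(ds, n_boot = 50), ">= 100")
  expect_error(bootstrap_curve_ci(ds[1], n_boot = 100), ">= 2 sessions")
})

test_that("too little data is rejected", {
  expect_error(fit_learning_curve(c(1, 0, 1)), "at least 10")
})
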