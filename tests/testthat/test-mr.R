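test_that("Wald ratio matches the delta-method closed form and a bootstrap oracle", {
  res <- wald_ratio(0.2, 0.02, 0.1, 0.02)
  expect_equal(res$b, 0.5)
  expect_equal(res$se, sqrt(0.02^2 / 0.2^2 + 0.1^2 * 0.02^2 / 0.2^4))
  expect_equal(res$se, 0.1118034, tolerance = 1e-6)
  # parametric bootstrap of the ratio distribution (independent oracle)
  set.seed(42)
  draws <- (0.1 + rnorm(2e5, 0, 0.02)) / (0.2 + rnorm(2e5, 0, 0.02))
  expect_equal(res$se, sd(draws), tolerance = 0.05)
  # by = 0: null estimate, p = 1
  null <- wald_ratio(0.2, 0.02, 0, 0.02)
  expect_equal(null$b, 0)
  expect_equal(null$p, 1)
  # negating bx negates the estimate, se unchanged
  neg <- wald_ratio(-0.2, 0.02, 0.1, 0.02)
  expect_equal(neg$b, -res$b)
  expect_equal(neg$se, res$se)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.02), "bx = 0")
})

test_that("IVW on duplicated instruments reduces to the Wald ratio", {
  w <- wald_ratio(0.2, 0.02, 0.1, 0.02)
  dup <- ivw(rep(0.2, 2), rep(0.02, 2), rep(0.1, 2), rep(0.02, 2))
  expect_equal(dup$b, w$b)
  expect_equal(dup$Q, 0)
  # fixed-effect se of the duplicated pair is the single-variant
  # 1/sqrt(w bx^2) scaled by 1/sqrt(2)
  single_se <- 1 / sqrt(0.2^2 / 0.02^2)
  expect_equal(dup$se, single_se / sqrt(2))
  expect_error(ivw(0.2, 0.02, 0.1, 0.02), "k >= 2")
})

test_that("IVW recovers the true effect with near-nominal CI coverage", {
  alpha <- 0.2
  reps <- 500
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- sim_independent_instruments(10, alpha, 20000, 50000, seed = 1000 + r)
    fit <- ivw(d$bx, d$sx, d$by, d$sy)
    est[r] <- fit$b
    se[r] <- fit$se
  }
  expect_lt(abs(mean(est) - alpha), 0.01)
  covered <- abs(est - alpha) <= 1.96 * se
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("Q is null-calibrated and se inflation engages under pleiotropic noise", {
  reps <- 400
  k <- 10
  qs <- numeric(reps)
  for (r in seq_len(reps)) {
    # null causal effect: outcome noise is the only residual source, so the
    # weights are exactly right and Q ~ chi-square(k - 1)
    d <- sim_independent_instruments(k, 0, 20000, 50000, seed = 7000 + r)
    qs[r] <- ivw(d$bx, d$sx, d$by, d$sy)$Q
  }
  expect_lt(abs(mean(qs) - (k - 1)), 3 * sqrt(2 * (k - 1) / reps))
  # per-variant pleiotropic noise inflates Q and the random-effects se
  set.seed(99)
  d <- sim_independent_instruments(k, 0.2, 20000, 50000, seed = 31,
                                   pleio = rnorm(k, 0, 0.02))
  fit_re <- ivw(d$bx, d$sx, d$by, d$sy)
  fit_fe <- ivw(d$bx, d$sx, d$by, d$sy, random_effects = FALSE)
  expect_gt(fit_re$Q / fit_re$Q_df, 1)
  expect_gt(fit_re$se, fit_fe$se)
})

test_that("Egger fits exact data exactly and recovers directional pleiotropy", {
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.3 * bx
  fit <- egger(bx, rep(0.01, 3), by, rep(0.01, 3))
  expect_equal(fit$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(fit$b, 0.3, tolerance = 1e-12)
  expect_error(egger(bx[1:2], rep(0.01, 2), by[1:2], rep(0.01, 2)),
               "at least 3")
  # constant pleiotropy c appears as the intercept (simulation oracle)
  cc <- 0.05
  reps <- 300
  ints <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- sim_independent_instruments(10, 0.2, 20000, 50000, seed = 500 + r,
                                     z_range = c(5, 25), pleio = rep(cc, 10))
    ints[r] <- egger(d$bx, d$sx, d$by, d$sy)$egger_intercept
  }
  expect_lt(abs(mean(ints) - cc), 4 * sd(ints) / sqrt(reps) + 0.002)
})

test_that("Egger orientation makes the fit invariant to exposure sign flips", {
  d <- sim_independent_instruments(8, 0.3, 20000, 50000, seed = 77)
  flip <- c(1, 4)
  bx2 <- d$bx; by2 <- d$by
  bx2[flip] <- -bx2[flip]; by2[flip] <- -by2[flip]
  f1 <- egger(d$bx, d$sx, d$by, d$sy)
  f2 <- egger(bx2, d$sx, by2, d$sy)
  expect_equal(f1$b, f2$b)
  expect_equal(f1$egger_intercept, f2$egger_intercept)
})

test_that("BH q-values and Bonferroni gates follow the step-up oracle", {
  adj <- adjust_pvalues(c(0.01, 0.02, 0.03), alpha = 0.05,
                        n_tests_bonferroni = 3)
  expect_equal(adj$q_values, rep(0.03, 3))
  # q-values are monotone in sorted p order and bounded by 1
  set.seed(8)
  p <- runif(50)^2
  adj2 <- adjust_pvalues(p)
  o <- order(p)
  expect_true(all(diff(adj2$q_values[o]) >= -1e-15))
  expect_true(all(adj2$q_values <= 1))
  # empty input: empty result
  expect_length(adjust_pvalues(numeric(0))$q_values, 0)
})

test_that("the two analysis-wide Bonferroni thresholds print as reported", {
  primary <- adjust_pvalues(0.01, alpha = 0.05, n_tests_bonferroni = 24598)
  expect_equal(signif(primary$bonferroni_threshold, 1), 2e-06)
  reverse <- adjust_pvalues(0.01, alpha = 0.05, n_tests_bonferroni = 7 * 736)
  expect_equal(signif(reverse$bonferroni_threshold, 2), 9.7e-06)
  # gates use the exact ratio, not the rounded display value
  expect_equal(primary$bonferroni_threshold, 0.05 / 24598)
})
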