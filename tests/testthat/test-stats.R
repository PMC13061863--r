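test_that("the one-sided binomial p-value matches direct enumeration", {
  # worked instance: n = 30, 20 default successes, 27 custom successes
  bt <- binomial_improvement_test(30, 20, 27)
  j <- 27:30
  oracle <- sum(choose(30, j) * (2 / 3)^j * (1 / 3)^(30 - j))
  expect_equal(bt$p_value, oracle, tolerance = 1e-12)
  expect_equal(bt$p_hat, 2 / 3)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    kd <- sample(0:n, 1)
    kc <- sample(0:n, 1)
    bt <- binomial_improvement_test(n, kd, kc)
    j <- kc:n
    oracle <- sum(choose(n, j) * (kd / n)^j * (1 - kd / n)^(n - j))
    expect_equal(bt$p_value, min(1, oracle), tolerance = 1e-10)
  }
})

test_that("binomial test degenerate cases behave as probability dictates", {
  expect_equal(binomial_improvement_test(12, 7, 0)$p_value, 1)  # P(X >= 0)
  expect_equal(binomial_improvement_test(12, 12, 5)$p_value, 1) # p_hat = 1
  expect_equal(binomial_improvement_test(12, 0, 0)$p_value, 1)
  expect_equal(binomial_improvement_test(12, 0, 1)$p_value, 0)
  expect_error(binomial_improvement_test(0, 0, 0), "positive")
  expect_error(binomial_improvement_test(10, 11, 0), "0..n")
})

test_that("the p-value is non-increasing in the custom success count", {
  for (n in c(10, 30, 47)) {
    kd <- round(n * 0.6)
    p <- vapply(0:n, function(kc)
      binomial_improvement_test(n, kd, kc)$p_value, numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("closed-form summation agrees with Monte-Carlo estimates", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    kd <- sample(1:(n - 1), 1)
    kc <- sample(0:n, 1)
    p <- binomial_improvement_test(n, kd, kc)$p_value
    draws <- rbinom(1e5, n, kd / n)
    mc <- mean(draws >= kc)
    se <- sqrt(max(mc * (1 - mc), 1e-6) / 1e5)
    expect_lt(abs(p - mc), 3 * se + 1e-3)
  }
})

test_that("matching performance is never significant by itself", {
  for (n in c(5, 10, 30, 60, 120)) {
    for (kd in unique(round(n * c(0.2, 0.5, 0.8)))) {
      if (kd <= 0 || kd >= n) next
      expect_gt(binomial_improvement_test(n, kd, kd)$p_value, 0.05)
    }
  }
})

test_that("group summaries aggregate paired improvements with bootstrap CIs", {
  res <- data.frame(subject = sprintf("s%02d", 1:12),
                    group = rep(c("g1", "g2"), each = 6),
                    acc_default = c(rep(0.5, 6), rep(0.9, 6)),
                    acc_custom = c(rep(0.8, 6), rep(0.9, 6)),
                    p_value = c(rep(0.01, 6), rep(0.7, 6)))
  gs <- summarize_groups(res, n_boot = 500, seed = 2)
  g1 <- gs[gs$group == "g1", ]
  expect_equal(g1$mean_improvement, 0.3)
  expect_equal(c(g1$ci_lower, g1$ci_upper), c(0.3, 0.3))  # constant shift
  expect_identical(g1$n_significant, 6L)
  expect_identical(gs[gs$group == "g2", ]$n_significant, 0L)
  gs2 <- summarize_groups(res, n_boot = 500, seed = 2)
  expect_equal(gs, gs2)
  expect_error(summarize_groups(res[, -2]), "must have columns")
})

test_that("bootstrap CIs separate a shifted group from a null group", {
  set.seed(33)
  imp_pos <- 0.4 + rnorm(15, sd = 0.1)   # severe-like paired improvements
  imp_null <- rnorm(15, sd = 0.1)        # control-like
  res <- data.frame(subject = sprintf("s%02d", 1:30),
                    group = rep(c("severe", "control"), each = 15),
                    acc_default = 0.4,
                    acc_custom = 0.4 + c(imp_pos, imp_null),
                    p_value = 0.5)
  gs <- summarize_groups(res, n_boot = 1000, seed = 3)
  sev <- gs[gs$group == "severe", ]
  ctl <- gs[gs$group == "control", ]
  expect_gt(sev$ci_lower, 0)
  expect_lt(ctl$ci_lower, 0)
  expect_gt(ctl$ci_upper, 0)
})
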