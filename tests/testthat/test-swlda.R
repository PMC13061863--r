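test_that("stepwise selection matches an lm-based reference implementation", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 80; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    beta <- c(2, -1.5, 0, 0, 1, 0, 0, 0)
    y <- sign(drop(X %*% beta) + rnorm(n))
    ref <- naive_stepwise(X, y)
    mdl <- fit_swlda(raw_fm(X, y))
    expect_identical(mdl$included, ref$included)
    expect_equal(mdl$weights, ref$weights, tolerance = 1e-8)
    expect_equal(mdl$intercept, ref$intercept, tolerance = 1e-8)
  }
})

test_that("with thresholds at 1 and a full-rank design stepwise is plain OLS", {
  set.seed(4)
  X <- matrix(rnorm(300 * 12), 300, 12)
  y <- rep(c(1, -1), 150)
  mdl <- fit_swlda(raw_fm(X, y),
                   swlda_config(max_features = 12, p_enter = 1, p_remove = 1))
  expect_identical(sort(mdl$included), 1:12)
  ls <- stats::lsfit(X, y)
  expect_lt(max(abs(mdl$weights - ls$coefficients[-1][mdl$included])), 1e-8)
  expect_lt(abs(mdl$intercept - ls$coefficients[1]), 1e-8)
})

test_that("degenerate inputs are rejected with meaningful conditions", {
  set.seed(5)
  X <- matrix(rnorm(40 * 4), 40, 4)
  expect_error(fit_swlda(raw_fm(X, rep(1, 40))), "both classes")
  # no feature can meet an absurdly strict entry criterion
  expect_error(fit_swlda(raw_fm(X, rep(c(1, -1), 20)),
                         swlda_config(p_enter = 1e-16, p_remove = 1e-15)),
               "could not calibrate",
               class = "p300select_calibration_failure")
  # collinear duplicate columns are skipped, not fatal
  X2 <- cbind(X, X[, 1])
  mdl <- fit_swlda(raw_fm(X2, sign(X2[, 1] + rnorm(40, sd = .3))),
                   swlda_config(p_enter = .9, p_remove = .95))
  expect_false(all(c(1, 5) %in% mdl$included))
})

test_that("the feature cap is respected on noise designs", {
  set.seed(6)
  X <- matrix(rnorm(400 * 60), 400, 60)
  y <- rep(c(1, -1), 200)
  mdl <- tryCatch(fit_swlda(raw_fm(X, y), swlda_config(max_features = 5)),
                  p300select_calibration_failure = function(e) NULL)
  if (!is.null(mdl)) expect_lte(length(mdl$included), 5L)
})

test_that("high-SNR separable sessions reach perfect resubstitution accuracy", {
  es <- toy_session(n_trials = 4, noise_sd = 0.5, amp = 8, seed = 15)
  fm <- extract_features(es)
  mdl <- fit_swlda(fm)
  ts <- score_trials(mdl, fm)
  expect_equal(accuracy(classify(ts), ts$targets), 1)
  # independent check that the epochs really are linearly separable:
  # ordinary LDA on the same features also classifies every epoch
  skip_if_not_installed("MASS")
  keep <- mdl$included
  ld <- MASS::lda(fm$X[, keep, drop = FALSE], grouping = factor(fm$y))
  expect_gte(mean(predict(ld)$class == factor(fm$y)), 0.99)
})

test_that("trial scoring equals a brute-force accumulation oracle", {
  es <- toy_session(n_trials = 3, noise_sd = 3, amp = 4, seed = 16)
  fm <- extract_features(es)
  mdl <- fit_swlda(fm)
  for (r in c(1L, 4L, 10L)) {
    ts <- score_trials(mdl, fm, r)
    brute <- matrix(0, 3, 4)
    for (e in seq_along(fm$y)) {
      sc <- sum(fm$X[e, mdl$included] * mdl$weights) + mdl$intercept
      if (fm$occurrence[e] <= r)
        brute[fm$trial[e], fm$choice[e]] <- brute[fm$trial[e], fm$choice[e]] + sc
    }
    expect_equal(unname(ts$sums), brute, tolerance = 1e-10)
  }
})

test_that("zero weights score the intercept r times and ties go low", {
  es <- toy_session(n_trials = 2, noise_sd = 1, seed = 17)
  fm <- extract_features(es)
  mdl <- fit_swlda(fm)
  mdl$weights[] <- 0
  mdl$intercept <- 2.5
  ts <- score_trials(mdl, fm, r = 7)
  expect_equal(unname(ts$sums), matrix(2.5 * 7, 2, 4))
  expect_identical(classify(ts), c(1L, 1L))  # exact tie -> lowest choice
})

test_that("accuracy is the plain fraction correct", {
  expect_identical(accuracy(c(1L, 2L), c(1L, 2L)), 1)
  expect_identical(accuracy(c(1L, 2L), c(2L, 1L)), 0)
  expect_identical(accuracy(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 1L)), 0.75)
  expect_error(accuracy(1L, c(1L, 2L)))
})

test_that("the flash-count tie-break scans downward from the full count", {
  targets <- c(1L, 2L)
  base <- array(0, c(2, 4, 10))
  base[cbind(1:2, targets, 1)] <- 1       # both right at every r
  a <- trial_scores(base, 10, targets)

  # differ already at r = 10
  b10 <- base; b10[2, 2, 10] <- -2; b10[2, 1, 10] <- 2
  res <- break_tie_scores(a, trial_scores(b10, 10, targets))
  expect_identical(res$r_used, 10L)
  expect_false(res$tie)
  expect_gt(res$acc_a, res$acc_b)

  # tied at 10 (both perfect), differ first at r = 9
  b9 <- base
  b9[2, 2, 9] <- -3; b9[2, 1, 9] <- 3   # wrong at r = 9, rescued at r = 10
  b9[2, 2, 10] <- 6
  res <- break_tie_scores(a, trial_scores(b9, 10, targets))
  expect_identical(res$r_used, 9L)
  expect_identical(c(res$acc_a, res$acc_b), c(1, 0.5))

  # identical scores never break the tie
  res <- break_tie_scores(a, trial_scores(base, 10, targets))
  expect_true(res$tie)
  expect_identical(res$r_used, 1L)
  expect_identical(res$acc_a, res$acc_b)

  expect_error(break_tie_scores(a, trial_scores(base, 10, c(2L, 1L))),
               "same trials")
})

test_that("break_tie_by_flashes wraps model scoring on a shared session", {
  es <- toy_session(n_trials = 3, noise_sd = 2, amp = 5, seed = 18)
  fm <- extract_features(es)
  mdl <- fit_swlda(fm)
  res <- break_tie_by_flashes(mdl, mdl, fm, fm)
  expect_true(res$tie)
  expect_identical(res$r_used, 1L)
})

test_that("resubstitution is optimistic on noise while CV stays near chance", {
  # the reason calibration accuracy is cross-validated in this package
  es <- toy_session(n_trials = 20, channels = standard_montage()$default8,
                    amp = 0, noise_sd = 5, seed = 19)
  fm <- extract_features(es)
  resub <- calibrate_subset(fm, fm$channels, method = "resubstitution")
  cv <- calibrate_subset(fm, fm$channels, method = "cv")
  expect_gt(resub$accuracy, 0.5)   # far above chance despite zero signal
  expect_lt(cv$accuracy, 0.55)     # CV estimate stays near 0.25
})

test_that("model serialization writes valid JSON", {
  es <- toy_session(n_trials = 2, noise_sd = 1, amp = 5, seed = 20)
  fm <- extract_features(es)
  mdl <- fit_swlda(fm)
  path <- withr::local_tempfile(fileext = ".json")
  write_swlda_json(mdl, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$weights, mdl$weights)
  expect_identical(as.integer(j$included), mdl$included)
})
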