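test_that("forward selection finds the single informative channel first", {
  # signal confined to C5's focus; Fz/Pz/Oz carry noise only
  es <- toy_session(n_trials = 6, channels = c("Fz", "C5", "Pz", "Oz"),
                    spread = 0.12, amp = 6, noise_sd = 4, seed = 21)
  fs <- forward_select(es, selection_config(M = 2))
  expect_identical(fs$order[1], "C5")
  ev1 <- fs$evaluations[[1]]
  expect_identical(names(which.max(ev1)), "C5")
  expect_gt(ev1[["C5"]], max(ev1[setdiff(names(ev1), "C5")]) + 0.1)
})

test_that("every greedy step attains the maximum recorded accuracy and an
           independent re-evaluation agrees", {
  es <- toy_session(n_trials = 6, channels = c("C5", "C3", "Cz", "Pz"),
                    amp = 5, noise_sd = 4, seed = 22)
  fm <- extract_features(es)
  fs <- forward_select(fm, selection_config(M = 3))
  ev <- swlda_evaluator(fm)  # same deterministic evaluator, fresh state
  for (step in seq_len(3)) {
    e <- fs$evaluations[[step]]
    expect_identical(fs$order[step], names(which.max(e)))
    expect_equal(fs$accuracy_trajectory[step], max(e))
    chosen_before <- fs$order[seq_len(step - 1)]
    redo <- ev(lapply(names(e), function(ch) c(chosen_before, ch)))
    expect_equal(unname(redo), unname(e))
  }
})

test_that("selecting the whole pool returns a permutation of it", {
  es <- toy_session(n_trials = 4, amp = 5, noise_sd = 3, seed = 23)
  fs <- forward_select(es, selection_config(M = 4))
  expect_setequal(fs$order, es$montage$names)
  expect_length(fs$accuracy_trajectory, 4L)
})

test_that("exhaustive search enumerates exactly choose(n, M) subsets", {
  es <- toy_session(n_trials = 4, amp = 5, noise_sd = 3, seed = 24)
  ex <- exhaustive_select(es, selection_config(M = 2))
  expect_identical(ex$n_evaluated, 6L)
  ex_all <- exhaustive_select(es, selection_config(M = 4))
  expect_setequal(ex_all$subset, es$montage$names)
  expect_error(
    exhaustive_select(es, selection_config(M = 2, max_combinations = 3L)),
    "refusing")
})

test_that("consensus scoring reproduces the worked rank-score instance", {
  cr <- score_fold_orders(list(c("A", "B"), c("B", "C")), M = 2,
                          pool = c("A", "B", "C", "D"))
  expect_identical(cr$scores, c(A = 2, B = 3, C = 1, D = 0))
  expect_identical(cr$chosen, c("B", "A"))
})

test_that("identical folds concentrate the consensus on one order", {
  cr <- score_fold_orders(rep(list(c("C", "A", "D")), 5), M = 3,
                          pool = c("A", "B", "C", "D"))
  expect_identical(cr$chosen, c("C", "A", "D"))
  expect_identical(unname(cr$scores[c("C", "A", "D")]), c(15, 10, 5))
  expect_identical(unname(cr$scores["B"]), 0)
})

test_that("consensus ties break by best rank, then montage order", {
  # A, B and C all score 2; best rank favours A and C over B
  cr <- score_fold_orders(list(c("A", "B"), c("C", "B")), M = 2,
                          pool = c("A", "B", "C", "D"))
  expect_identical(unname(cr$scores), c(2, 2, 2, 0))
  expect_identical(cr$chosen, c("A", "C"))
  cr2 <- score_fold_orders(list("B", "C"), M = 1,
                           pool = c("A", "B", "C", "D"))
  expect_identical(cr2$chosen, "B")  # equal score and rank: montage order
  expect_error(score_fold_orders(list(c("A", "A")), 2, c("A", "B")),
               "duplicate")
  expect_error(score_fold_orders(list("E"), 1, c("A", "B")),
               "outside the pool")
})

test_that("consensus scoring equals brute-force formula evaluation", {
  pool <- LETTERS[1:10]
  set.seed(99)
  for (i in 1:100) {
    M <- sample(2:6, 1)
    n_folds <- sample(2:8, 1)
    orders <- replicate(n_folds, sample(pool, sample(seq_len(M), 1)),
                        simplify = FALSE)
    cr <- score_fold_orders(orders, M, pool)
    brute <- sapply(pool, function(e) {
      s <- 0
      for (ord in orders) {
        k <- match(e, ord)
        if (!is.na(k)) s <- s + max(0, M - k + 1)
      }
      s
    })
    expect_identical(unname(cr$scores), unname(brute))
    expect_gte(min(cr$scores[cr$chosen]),
               max(c(cr$scores[setdiff(pool, cr$chosen)], 0)))
  }
})

test_that("consensus selection composes fold orders with the rank formula", {
  es <- toy_session(n_trials = 3, amp = 6, noise_sd = 3, seed = 25)
  fm <- extract_features(es)
  cs <- consensus_select(fm, selection_config(M = 2))
  expect_length(cs$fold_results, 3L)
  manual <- score_fold_orders(lapply(cs$fold_results, `[[`, "order"),
                              M = 2, pool = fm$channels)
  expect_identical(cs$consensus$scores, manual$scores)
  expect_identical(cs$chosen, manual$chosen)
  expect_s3_class(cs$model, "swlda_model")
  expect_true(all(cs$model$feature_map$channel %in% cs$chosen))
  fm1 <- p300select:::subset_trials(fm, 1)
  expect_error(consensus_select(fm1, selection_config(M = 2)),
               "at least 2 trials")
})

test_that("subset-size curves locate the 95%-of-own-accuracy point", {
  mk <- function(traj) structure(list(order = LETTERS[seq_along(traj)],
                                      accuracy_trajectory = traj,
                                      evaluations = list(), M = length(traj),
                                      pool = LETTERS),
                                 class = "selection_result")
  expect_identical(subset_size_curve(mk(rep(0.8, 8)))$electrodes_needed, 1L)
  expect_identical(
    subset_size_curve(mk(c(0.4, 0.6, 0.8, 0.9, 0.95, 0.96, 0.96, 0.96)))$electrodes_needed,
    5L)
  expect_identical(subset_size_curve(mk(rep(0, 8)))$electrodes_needed, 1L)
})

test_that("the generalization experiment is deterministic and honours its
           identity control", {
  es <- toy_session(n_trials = 63, channels = c("C5", "C3", "Cz", "Pz"),
                    amp = 6, noise_sd = 3, seed = 26)
  cfg <- selection_config(M = 2)
  g1 <- generalization_experiment(es, cfg, seed = 2, n_calibration = 40,
                                  n_test = 20,
                                  default_subset = c("C5", "C3"))
  g2 <- generalization_experiment(es, cfg, seed = 2, n_calibration = 40,
                                  n_test = 20,
                                  default_subset = c("C5", "C3"))
  expect_identical(g1$test_trials, g2$test_trials)
  expect_identical(g1$chosen, g2$chosen)
  expect_identical(g1$testing, g2$testing)
  # identity control: restrict the pool to the comparison subset
  gid <- generalization_experiment(
    es, selection_config(M = 2, pool = c("C5", "C3")), seed = 2,
    n_calibration = 40, n_test = 20, default_subset = c("C5", "C3"))
  expect_setequal(gid$chosen, c("C5", "C3"))
  expect_equal(gid$calibration$custom, gid$calibration$default)
  expect_equal(gid$testing$custom, gid$testing$default)
  expect_error(generalization_experiment(toy_session(n_trials = 4), cfg,
                                         seed = 1),
               "at least 60")
})
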