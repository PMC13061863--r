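#' Electrode selection configuration
#'
#' @param M target subset size.
#' @param pool candidate electrode names; `NULL` means every montage channel.
#'   The pool is kept in montage order, which is also the deterministic
#'   tie-break when two candidates reach equal accuracy.
#' @param method accuracy estimator passed to the evaluator
#'   (`"cv"` or `"resubstitution"`).
#' @param n_folds folds of the cross-validated evaluator.
#' @param criterion ranking criterion of the evaluator: `"flash_mean"`
#'   (accuracy averaged over flash counts; default) or `"final"` (accuracy
#'   at the full flash count). See [swlda_evaluator()].
#' @param r maximum flash repetitions used by the evaluator (default: all).
#' @param max_combinations guard for [exhaustive_select()].
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(M = 8L, pool = NULL,
                             method = c("cv", "resubstitution"),
                             n_folds = 3L,
                             criterion = c("flash_mean", "final"),
                             r = NULL, max_combinations = 20000L) {
  structure(list(M = as.integer(M), pool = pool,
                 method = match.arg(method), n_folds = as.integer(n_folds),
                 criterion = match.arg(criterion), r = r,
                 max_combinations = as.integer(max_combinations)),
            class = "selection_config")
}

resolve_pool <- function(fm, cfg) {
  pool <- if (is.null(cfg$pool)) fm$channels
          else fm$channels[fm$channels %in% cfg$pool]
  if (length(pool) < length(cfg$pool %||% pool))
    stop("pool contains channels absent from the feature matrix")
  if (cfg$M < 1L || cfg$M > length(pool))
    stop("M must satisfy 1 <= M <= |pool|")
  pool
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_feature_matrix <- function(x, feature_cfg = feature_config()) {
  if (inherits(x, "feature_matrix")) x
  else if (inherits(x, "epoch_set")) extract_features(x, feature_cfg)
  else stop("expected an epoch_set or feature_matrix")
}

#' Greedy forward electrode selection
#'
#' Starting from an empty chosen set, each step evaluates the calibration
#' accuracy of `chosen + {candidate}` for every remaining candidate and moves
#' the arg-max candidate (ties: earliest in montage order) into the chosen
#' set, until `M` electrodes are chosen. A candidate whose SWLDA fit fails to
#' calibrate scores accuracy 0.
#'
#' @param x an [epoch_set()] or [extract_features()] result.
#' @param cfg a [selection_config()].
#' @param swlda a [swlda_config()].
#' @param evaluator optional `function(sets) -> accuracies` overriding the
#'   default split-half SWLDA evaluator (see [swlda_evaluator()]).
#' @return an object of class `selection_result`: `order` (electrodes in
#'   order of addition), `accuracy_trajectory`, and `evaluations` (per step,
#'   the accuracy of every candidate).
#' @export
forward_select <- function(x, cfg = selection_config(),
                           swlda = swlda_config(), evaluator = NULL) {
  fm <- as_feature_matrix(x)
  pool <- resolve_pool(fm, cfg)
  if (is.null(evaluator)) {
    state <- eval_state(fm, swlda, cfg$method, cfg$n_folds, cfg$r, cfg$criterion)
    evaluator <- function(sets) eval_channel_sets(state, sets)
  }
  chosen <- character(0)
  trajectory <- numeric(0)
  evaluations <- vector("list", cfg$M)
  for (step in seq_len(cfg$M)) {
    avail <- setdiff(pool, chosen)
    sets <- lapply(avail, function(e) c(chosen, e))
    acc <- evaluator(sets)
    names(acc) <- avail
    if (step == 1L && all(acc == 0))
      stop(errorCondition("every candidate failed to calibrate at step 1",
                          class = c("p300select_selection_failure",
                                    "error", "condition")))
    best <- which.max(acc)  # first max = earliest in montage order
    chosen <- c(chosen, avail[best])
    trajectory <- c(trajectory, acc[[best]])
    evaluations[[step]] <- acc
  }
  structure(list(order = chosen, accuracy_trajectory = trajectory,
                 evaluations = evaluations, M = cfg$M, pool = pool),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n  order:",
      paste(x$order, collapse = " "), "\n  accuracy:",
      paste(sprintf("%.3f", x$accuracy_trajectory), collapse = " "), "\n")
  invisible(x)
}

#' Exhaustive subset search (test oracle)
#'
#' Evaluates every `M`-subset of the pool with the same evaluator as
#' [forward_select()] and returns the arg-max (ties: lexicographically first
#' in montage order). Guarded by `cfg$max_combinations`.
#'
#' @inheritParams forward_select
#' @return a list: `subset`, `accuracy`, `n_evaluated`.
#' @export
exhaustive_select <- function(x, cfg = selection_config(),
                              swlda = swlda_config(), evaluator = NULL) {
  fm <- as_feature_matrix(x)
  pool <- resolve_pool(fm, cfg)
  n_comb <- choose(length(pool), cfg$M)
  if (n_comb > cfg$max_combinations)
    stop("refusing to enumerate ", n_comb, " subsets (guard: ",
         cfg$max_combinations, ")")
  if (is.null(evaluator)) {
    state <- eval_state(fm, swlda, cfg$method, cfg$n_folds, cfg$r, cfg$criterion)
    evaluator <- function(sets) eval_channel_sets(state, sets)
  }
  combos <- utils::combn(pool, cfg$M, simplify = FALSE)
  acc <- evaluator(combos)
  best <- which.max(acc)
  list(subset = combos[[best]], accuracy = acc[[best]],
       n_evaluated = length(combos))
}

#' Consensus scoring of per-fold selection orders
#'
#' Each electrode receives, per fold, the score `max(0, M - k + 1)` where `k`
#' is its 1-based addition rank in that fold (0 when unranked); scores are
#' summed over folds and the top `M` electrodes are chosen. Ties at the M-th
#' slot are broken by the better (smaller) best rank across folds, then by
#' montage order.
#'
#' @param fold_orders list of character vectors (per-fold addition orders,
#'   each at most `M` long, no duplicates within a fold).
#' @param M target subset size.
#' @param pool electrode names in montage order.
#' @return an object of class `consensus_result`: named `scores` over the
#'   pool, `chosen` (top `M`), and `fold_orders`.
#' @export
score_fold_orders <- function(fold_orders, M, pool) {
  M <- as.integer(M)
  scores <- stats::setNames(numeric(length(pool)), pool)
  best_rank <- stats::setNames(rep(Inf, length(pool)), pool)
  for (ord in fold_orders) {
    ord <- as.character(ord)
    if (anyDuplicated(ord)) stop("duplicate electrode within a fold order")
    if (!all(ord %in% pool)) stop("fold order contains electrodes outside the pool")
    k <- seq_along(ord)
    scores[ord] <- scores[ord] + pmax(0, M - k + 1)
    best_rank[ord] <- pmin(best_rank[ord], k)
  }
  ranking <- order(-scores, best_rank, seq_along(pool))
  structure(list(scores = scores, chosen = pool[ranking[seq_len(M)]],
                 fold_orders = fold_orders, M = M, pool = pool),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> chosen:", paste(x$chosen, collapse = " "), "\n")
  invisible(x)
}

#' Consensus electrode selection over leave-one-trial-out folds
#'
#' For each of the `N` leave-one-trial-out folds, greedy forward selection is
#' run on the remaining `N - 1` trials; the per-fold addition orders are
#' aggregated with [score_fold_orders()], and the final SWLDA model is fit on
#' all `N` trials restricted to the chosen `M` electrodes.
#'
#' @inheritParams forward_select
#' @return a list of class `consensus_selection`: the `consensus`
#'   ([score_fold_orders()] result), `model` (final SWLDA), `chosen`, and
#'   `fold_results` (per-fold [forward_select()] outputs).
#' @export
consensus_select <- function(x, cfg = selection_config(),
                             swlda = swlda_config()) {
  fm <- as_feature_matrix(x)
  pool <- resolve_pool(fm, cfg)
  N <- length(fm$target_choice)
  if (N < 2L) stop("consensus selection needs at least 2 trials")
  fold_results <- vector("list", N)
  for (t in seq_len(N)) {
    # Each fold uses its own (deterministically shuffled) cross-validation
    # partition so that evaluator noise decorrelates across the N folds and
    # the consensus scores average over independent partitions.
    fm_t <- subset_trials(fm, setdiff(seq_len(N), t))
    state_t <- eval_state(fm_t, swlda, cfg$method, cfg$n_folds, cfg$r,
                          cfg$criterion, fold_shuffle = t)
    ev <- function(sets) eval_channel_sets(state_t, sets)
    fold_results[[t]] <- tryCatch(
      forward_select(fm_t, cfg, swlda, evaluator = ev),
      p300select_selection_failure = function(e)
        stop(errorCondition(paste0("selection failed in fold ", t, ": ",
                                   conditionMessage(e)),
                            class = c("p300select_selection_failure",
                                      "error", "condition"))))
  }
  consensus <- score_fold_orders(lapply(fold_results, `[[`, "order"),
                                 cfg$M, pool)
  model <- fit_swlda(fm, swlda,
                     columns = channel_columns(fm, consensus$chosen))
  structure(list(consensus = consensus, model = model,
                 chosen = consensus$chosen, fold_results = fold_results),
            class = "consensus_selection")
}

#' Accuracy as a function of subset size
#'
#' @param result a [forward_select()] result.
#' @return a list: `sizes`, `accuracy` (the trajectory), and
#'   `electrodes_needed`, the smallest size whose accuracy reaches 95% of the
#'   accuracy at the full subset size.
#' @export
subset_size_curve <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  traj <- result$accuracy_trajectory
  threshold <- 0.95 * traj[length(traj)]
  list(sizes = seq_along(traj), accuracy = traj,
       electrodes_needed = which(traj >= threshold)[1])
}

#' Holdout generalization experiment
#'
#' Randomly holds out `n_test` trials; runs [consensus_select()] on the
#' remaining calibration trials and fits the default-8 SWLDA on the same
#' trials; applies both models to the held-out trials. Calibration accuracy
#' is the split-half estimate on the calibration trials; testing accuracy is
#' the held-out trial accuracy at the full flash count, with the flash-count
#' tie-break applied to each comparison.
#'
#' @param es an [epoch_set()] with at least `n_calibration + n_test` trials.
#' @param cfg a [selection_config()]; its pool/M define the custom subset.
#' @param swlda a [swlda_config()].
#' @param feature_cfg a [feature_config()].
#' @param seed integer seed for the holdout draw.
#' @param n_calibration,n_test trial counts for the split.
#' @param default_subset electrode names of the comparison subset.
#' @return a list of class `generalization_report` with the chosen subset,
#'   per-arm calibration and testing accuracies, tie-break results, and the
#'   holdout trial indices.
#' @export
generalization_experiment <- function(es, cfg = selection_config(),
                                      swlda = swlda_config(),
                                      feature_cfg = feature_config(),
                                      seed = 1L, n_calibration = 40L,
                                      n_test = 20L,
                                      default_subset = es$montage$default8) {
  stopifnot(inherits(es, "epoch_set"))
  N <- n_trials(es)
  if (N < n_calibration + n_test)
    stop("need at least ", n_calibration + n_test, " trials, have ", N)
  test_trials <- with_seed(seed,
    sort(sample(seq_len(N), n_test)))
  cal_trials <- setdiff(seq_len(N), test_trials)[seq_len(n_calibration)]
  fm <- extract_features(es, feature_cfg)
  fm_cal <- subset_trials(fm, cal_trials)
  fm_test <- subset_trials(fm, test_trials)
  sel <- consensus_select(fm_cal, cfg, swlda)
  custom_cal <- calibrate_subset(fm_cal, sel$chosen, swlda, cfg$method, cfg$n_folds)
  default_cal <- calibrate_subset(fm_cal, default_subset, swlda, cfg$method, cfg$n_folds)
  default_model <- fit_swlda(fm_cal, swlda,
                             columns = channel_columns(fm_cal, default_subset))
  ts_custom <- score_trials(sel$model, fm_test)
  ts_default <- score_trials(default_model, fm_test)
  cal_tie <- break_tie_scores(custom_cal$scores, default_cal$scores)
  test_tie <- break_tie_scores(ts_custom, ts_default)
  structure(list(
    chosen = sel$chosen, default_subset = default_subset,
    consensus = sel$consensus, test_trials = test_trials,
    calibration = list(custom = custom_cal$accuracy,
                       default = default_cal$accuracy, tie_break = cal_tie),
    testing = list(custom = accuracy(classify(ts_custom), ts_custom$targets),
                   default = accuracy(classify(ts_default), ts_default$targets),
                   tie_break = test_tie),
    seed = seed), class = "generalization_report")
}
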