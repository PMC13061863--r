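# Calibration-accuracy machinery shared by subset calibration, greedy
# forward selection, exhaustive search and the consensus procedure.
#
# Calibration accuracy is estimated by deterministic cross-validation within
# the calibration trials: trials are dealt into interleaved folds by
# position, an SWLDA model is fit on the out-of-fold trials and scores the
# fold, and trial classification is evaluated over all trials. On noise-only
# data this estimate sits at chance, whereas resubstitution (also available)
# is strongly optimistic because the stepwise search overfits its own
# training epochs; see the methods vignette.

# Deal trial positions 1..n into k interleaved folds. A non-zero `shuffle`
# index deterministically permutes the trials first (seeded by the index);
# the consensus procedure uses the leave-one-trial-out fold index here so
# that each fold sees an independent cross-validation partition and
# partition noise averages out of the consensus scores.
cv_folds <- function(n_trials, k, shuffle = 0L) {
  pos <- seq_len(n_trials)
  if (shuffle > 0L)
    pos <- with_seed(907L + shuffle, sample(pos))
  lapply(seq_len(k), function(f) pos[seq_len(n_trials) %% k == (f %% k)])
}

# Precompute Gram matrices and epoch metadata for fast candidate evaluation.
# Supports leave-one-trial-out folds by Gram downdating.
eval_state <- function(fm, swlda = swlda_config(),
                       method = c("cv", "resubstitution"),
                       n_folds = 3L, r = NULL,
                       criterion = c("flash_mean", "final"),
                       fold_shuffle = 0L) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  n_tr <- length(fm$target_choice)
  if (is.null(r)) r <- fm$flashes_per_choice
  if (method == "cv" && n_tr < 2L)
    stop("cross-validation needs at least 2 trials")
  n_folds <- min(as.integer(n_folds), n_tr)
  folds <- if (method == "cv") cv_folds(n_tr, n_folds, fold_shuffle)
           else list(seq_len(n_tr))
  rows <- lapply(folds, function(h) which(fm$trial %in% h))
  grams <- lapply(rows, function(rw)
    bordered_gram(fm$X[rw, , drop = FALSE], fm$y[rw]))
  g_total <- Reduce(`+`, grams)
  list(fm = fm, method = method, r = as.integer(r), criterion = criterion,
       swlda = swlda, n_trials = n_tr, folds = folds, rows = rows,
       grams = grams, g_total = g_total)
}

# Evaluate candidate channel sets. Returns accuracies in [0, 1]; a set
# whose stepwise fit fails (in any fold) scores 0.
eval_channel_sets <- function(state, sets) {
  fm <- state$fm
  cfg <- state$swlda
  cols <- lapply(sets, function(chs) channel_columns(fm, chs))
  n_scored <- state$n_trials
  correct <- matrix(0L, length(sets), state$r)
  failed <- logical(length(sets))
  for (f in seq_along(state$folds)) {
    te_trials <- state$folds[[f]]
    te_rows <- state$rows[[f]]
    if (state$method == "cv") {
      G <- state$g_total - state$grams[[f]]
      n_train <- nrow(fm$X) - length(te_rows)
    } else {  # resubstitution: train and test on the same trials
      G <- state$g_total
      n_train <- nrow(fm$X)
    }
    cnt <- cpp_eval_sets(G, n_train, cols, fm$X, te_rows,
                         fm$trial, fm$choice, fm$occurrence,
                         fm$target_choice, te_trials, fm$n_choices,
                         state$r, cfg$max_features, cfg$p_enter,
                         cfg$p_remove, cfg$max_iterations, cfg$tol)
    failed <- failed | cnt[, 1] < 0L
    correct <- correct + pmax(cnt, 0L)
  }
  acc <- if (state$criterion == "flash_mean") rowMeans(correct) / n_scored
         else correct[, state$r] / n_scored
  acc[failed] <- 0
  acc
}

#' Calibration-accuracy evaluator for electrode subsets
#'
#' Returns a function mapping a list of electrode-name vectors to their
#' calibration accuracies on the trials of `fm`, estimated by deterministic
#' interleaved k-fold cross-validation (default) or resubstitution. This is
#' the evaluator used by [forward_select()] and [exhaustive_select()].
#'
#' With `criterion = "flash_mean"` (the default used for selection) the
#' returned value is the trial accuracy averaged over flash counts
#' `1..r` -- the area under the accuracy-versus-flash-count curve. This is a
#' finer-grained, lower-variance ranking criterion than the accuracy at the
#' full flash count (`criterion = "final"`), which takes only `n_trials + 1`
#' distinct values and therefore produces many exact ties between candidate
#' electrodes.
#'
#' @param fm a [extract_features()] result.
#' @param swlda a [swlda_config()].
#' @param method `"cv"` (default) or `"resubstitution"`.
#' @param n_folds folds for cross-validation (trials are dealt to folds by
#'   position, deterministically).
#' @param r maximum flash repetitions used when scoring trials (default:
#'   all).
#' @param criterion `"flash_mean"` (default) or `"final"`.
#' @return `function(sets)` where `sets` is a list of character vectors;
#'   returns a numeric vector of accuracies (0 for sets that fail to
#'   calibrate).
#' @export
swlda_evaluator <- function(fm, swlda = swlda_config(),
                            method = c("cv", "resubstitution"),
                            n_folds = 3L, r = NULL,
                            criterion = c("flash_mean", "final")) {
  state <- eval_state(fm, swlda, match.arg(method), n_folds, r,
                      match.arg(criterion))
  function(sets) eval_channel_sets(state, sets)
}

#' Calibrate one electrode subset
#'
#' Fits the deliverable SWLDA model on all trials restricted to `channels`,
#' and estimates calibration accuracy with occurrence-resolved trial scores
#' (interleaved k-fold cross-validation by default) so accuracy is available
#' at any flash count for tie-breaking.
#'
#' @inheritParams swlda_evaluator
#' @param channels electrode names.
#' @return a list of class `subset_calibration`: `channels`, `model` (fit on
#'   all trials; `NULL` if calibration failed), `scores` (a
#'   [trial_scores()]), `accuracy` (at the full flash count), `correct`
#'   (count of correct trials), `n_trials`, `failed`, `method`.
#' @export
calibrate_subset <- function(fm, channels, swlda = swlda_config(),
                             method = c("cv", "resubstitution"),
                             n_folds = 3L) {
  method <- match.arg(method)
  cols <- channel_columns(fm, channels)
  n_tr <- length(fm$target_choice)
  model <- tryCatch(fit_swlda(fm, swlda, columns = cols),
                    p300select_calibration_failure = function(e) NULL)
  failed <- is.null(model)
  sc <- rep(NA_real_, length(fm$y))
  if (!failed && method == "cv") {
    folds <- cv_folds(n_tr, min(as.integer(n_folds), n_tr))
    rows <- lapply(folds, function(h) which(fm$trial %in% h))
    grams <- lapply(rows, function(rw)
      bordered_gram(fm$X[rw, , drop = FALSE], fm$y[rw]))
    g_total <- Reduce(`+`, grams)
    for (f in seq_along(folds)) {
      n_train <- nrow(fm$X) - length(rows[[f]])
      fit <- cpp_stepwise_fit(g_total - grams[[f]], cols, n_train,
                              swlda$max_features, swlda$p_enter,
                              swlda$p_remove, swlda$max_iterations,
                              swlda$tol)
      if (!isTRUE(fit$ok)) { failed <- TRUE; break }
      sc[rows[[f]]] <- fm$X[rows[[f]], fit$included, drop = FALSE] %*%
        fit$weights + fit$intercept
    }
  } else if (!failed) {
    sc <- epoch_scores(model, fm)
  }
  if (failed) {
    return(structure(list(channels = channels, model = NULL, scores = NULL,
                          accuracy = 0, correct = 0L, n_trials = n_tr,
                          failed = TRUE, method = method),
                     class = "subset_calibration"))
  }
  arr <- occ_score_array(sc, fm$trial, fm$choice, fm$occurrence, n_tr,
                         fm$n_choices, fm$flashes_per_choice)
  ts <- trial_scores(arr, fm$flashes_per_choice, fm$target_choice)
  pred <- classify(ts)
  structure(list(channels = channels, model = model, scores = ts,
                 accuracy = accuracy(pred, ts$targets),
                 correct = sum(pred == ts$targets), n_trials = n_tr,
                 failed = FALSE, method = method),
            class = "subset_calibration")
}

#' @export
print.subset_calibration <- function(x, ...) {
  cat(sprintf("<subset_calibration> %s: accuracy %.3f (%d/%d trials, %s)%s\n",
              paste(x$channels, collapse = " "), x$accuracy, x$correct,
              x$n_trials, x$method,
              if (x$failed) " [calibration failed]" else ""))
  invisible(x)
}
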