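#' SWLDA configuration
#'
#' Stepwise linear discriminant analysis is realized as stepwise ordinary
#' least-squares regression of the coded class labels (+1 target, -1
#' non-target) on the feature columns: at each iteration the excluded column
#' with the smallest partial-F p-value enters if that p-value is below
#' `p_enter`, then any included column whose partial-F p-value exceeds
#' `p_remove` is removed, until a fixed point, the feature cap, or the
#' iteration safeguard is reached.
#'
#' @param max_features maximum number of included features.
#' @param p_enter entry threshold for the partial-F p-value.
#' @param p_remove removal threshold; must satisfy
#'   `0 < p_enter <= p_remove < 1` (strictly, `p_remove >= p_enter`) so a
#'   just-entered feature is not immediately removed.
#' @param max_iterations safeguard on add/remove iterations.
#' @param tol relative tolerance below which a candidate column is treated
#'   as collinear with the included set and skipped.
#' @return an object of class `swlda_config`.
#' @export
swlda_config <- function(max_features = 60L, p_enter = 0.10,
                         p_remove = 0.15, max_iterations = 300L,
                         tol = 1e-10) {
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove <= 1))
    stop("need 0 < p_enter <= p_remove <= 1")
  if (max_features < 1L) stop("max_features must be >= 1")
  structure(list(max_features = as.integer(max_features),
                 p_enter = p_enter, p_remove = p_remove,
                 max_iterations = as.integer(max_iterations), tol = tol),
            class = "swlda_config")
}

# bordered Gram matrix crossprod([1, X, y]) used by the sweep-based stepwise
bordered_gram <- function(X, y) crossprod(cbind(1, X, y))

# condition signalled when no feature meets p_enter (the session analogue of
# a participant who could not calibrate)
calibration_failure <- function(msg) {
  stop(errorCondition(msg, class = c("p300select_calibration_failure",
                                     "error", "condition")))
}

#' Fit a stepwise linear discriminant (SWLDA) model
#'
#' @param fm a [extract_features()] result (or any list with elements `X`,
#'   `y`, `feature_map`); both classes must be present.
#' @param cfg a [swlda_config()].
#' @param columns optional feature-column indices restricting the candidate
#'   pool (default: all columns).
#' @return an object of class `swlda_model`: `included` (feature columns in
#'   order of addition), `weights`, `intercept`, `config`, and the rows of
#'   `feature_map` for the included columns. Signals a classed error
#'   `p300select_calibration_failure` when no feature meets `p_enter`.
#' @export
fit_swlda <- function(fm, cfg = swlda_config(), columns = NULL) {
  y <- fm$y
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit SWLDA")
  if (min(table(y)) < 2L) stop("need at least 2 epochs per class")
  if (is.null(columns)) columns <- seq_len(ncol(fm$X))
  G <- bordered_gram(fm$X, y)
  fit <- cpp_stepwise_fit(G, as.integer(columns), nrow(fm$X),
                          cfg$max_features, cfg$p_enter, cfg$p_remove,
                          cfg$max_iterations, cfg$tol)
  if (!isTRUE(fit$ok))
    calibration_failure("no feature met the entry criterion; session could not calibrate")
  new_swlda_model(fit, cfg, fm)
}

new_swlda_model <- function(fit, cfg, fm) {
  structure(list(included = as.integer(fit$included),
                 weights = as.numeric(fit$weights),
                 intercept = as.numeric(fit$intercept),
                 rss = fit$rss, iterations = fit$iterations,
                 config = cfg,
                 feature_map = fm$feature_map[fit$included, , drop = FALSE],
                 channels = fm$channels),
            class = "swlda_model")
}

#' @export
print.swlda_model <- function(x, ...) {
  cat(sprintf("<swlda_model> %d features over %d channel(s)\n",
              length(x$included),
              length(unique(x$feature_map$channel))))
  invisible(x)
}

#' Serialize an SWLDA model to JSON
#'
#' @param model a [fit_swlda()] result.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_swlda_json <- function(model, path) {
  jsonlite::write_json(list(included = model$included,
                            weights = model$weights,
                            intercept = model$intercept,
                            feature_map = model$feature_map,
                            config = unclass(model$config)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# per-epoch discriminant scores
epoch_scores <- function(model, fm) {
  drop(fm$X[, model$included, drop = FALSE] %*% model$weights) + model$intercept
}

# occurrence-resolved score array [trial, choice, occurrence] from per-epoch
# scores; entries for (trial, choice, occ) pairs absent from `rows` are 0.
occ_score_array <- function(scores, trial, choice, occurrence, n_trials,
                            n_choices, max_occ) {
  arr <- array(0, c(n_trials, n_choices, max_occ))
  arr[cbind(trial, choice, occurrence)] <- scores
  arr
}

#' Score trials by summed flash responses
#'
#' Each flash epoch receives the discriminant score
#' `dot(weights, features) + intercept`; per (trial, choice) the scores of the
#' first `r` flashes of that choice, in presentation order, are summed.
#'
#' @param model a [fit_swlda()] result.
#' @param fm a [extract_features()] result containing the model's columns.
#' @param r number of flash repetitions used, `1 <= r <= flashes_per_choice`.
#' @return an object of class `trial_scores`: matrix `sums` (trial x choice),
#'   the occurrence-resolved array `occ_scores`, `r`, and per-trial `targets`.
#' @export
score_trials <- function(model, fm, r = fm$flashes_per_choice) {
  if (r < 1L || r > fm$flashes_per_choice)
    stop("r must be between 1 and flashes_per_choice")
  if (max(model$included) > ncol(fm$X))
    stop("feature matrix lacks columns required by the model")
  sc <- epoch_scores(model, fm)
  arr <- occ_score_array(sc, fm$trial, fm$choice, fm$occurrence,
                         length(fm$target_choice), fm$n_choices,
                         fm$flashes_per_choice)
  trial_scores(arr, r, fm$target_choice)
}

#' Construct trial scores from an occurrence-resolved score array
#'
#' @param occ_scores array `[trial, choice, occurrence]` of epoch scores.
#' @param r repetitions used for the summed score.
#' @param targets correct choice per trial.
#' @return a `trial_scores` object.
#' @export
trial_scores <- function(occ_scores, r, targets) {
  stopifnot(length(dim(occ_scores)) == 3L, r >= 1L, r <= dim(occ_scores)[3])
  sums <- occ_scores[, , 1L, drop = FALSE][, , 1L]
  if (!is.matrix(sums)) sums <- matrix(sums, dim(occ_scores)[1])
  if (r > 1L) for (j in 2:r) sums <- sums + occ_scores[, , j]
  structure(list(sums = sums, occ_scores = occ_scores, r = as.integer(r),
                 targets = as.integer(targets)),
            class = "trial_scores")
}

#' Classify trials from summed scores
#'
#' @param ts a [score_trials()] result.
#' @return integer vector: per trial, the choice with the maximal summed
#'   score; exact ties resolve to the lowest choice index.
#' @export
classify <- function(ts) {
  stopifnot(inherits(ts, "trial_scores"))
  max.col(ts$sums, ties.method = "first")
}

#' Fraction of correctly classified trials
#'
#' @param predictions integer vector of predicted choices.
#' @param targets integer vector of correct choices.
#' @return fraction correct in `[0, 1]`.
#' @export
accuracy <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets))
  mean(predictions == targets)
}

# accuracy of a trial_scores object at r repetitions
accuracy_at <- function(ts, r) {
  ts_r <- trial_scores(ts$occ_scores, r, ts$targets)
  accuracy(classify(ts_r), ts_r$targets)
}

#' Break an accuracy tie by reducing the flash count
#'
#' When two electrode subsets tie at the full flash count, the number of
#' flashes is decreased from the maximum and the accuracies are reported at
#' the first (largest) count at which the tie is broken. If the accuracies
#' never differ, `r_used = 1` is returned with `tie = TRUE`.
#'
#' @param ts_a,ts_b [trial_scores()] for the two subsets on the same trials.
#' @return a list: `acc_a`, `acc_b`, `r_used`, `tie`.
#' @export
break_tie_scores <- function(ts_a, ts_b) {
  stopifnot(inherits(ts_a, "trial_scores"), inherits(ts_b, "trial_scores"))
  if (!identical(dim(ts_a$occ_scores), dim(ts_b$occ_scores)) ||
      !identical(ts_a$targets, ts_b$targets))
    stop("trial scores must cover the same trials and targets")
  r_max <- dim(ts_a$occ_scores)[3]
  for (r in seq(r_max, 1L)) {
    acc_a <- accuracy_at(ts_a, r)
    acc_b <- accuracy_at(ts_b, r)
    if (acc_a != acc_b)
      return(list(acc_a = acc_a, acc_b = acc_b, r_used = r, tie = FALSE))
  }
  list(acc_a = accuracy_at(ts_a, 1L), acc_b = accuracy_at(ts_b, 1L),
       r_used = 1L, tie = TRUE)
}

#' @rdname break_tie_scores
#' @param model_a,model_b fitted [fit_swlda()] models.
#' @param fm_a,fm_b feature matrices for the two subsets covering the same
#'   trials (typically the same `fm`).
#' @export
break_tie_by_flashes <- function(model_a, model_b, fm_a, fm_b) {
  if (!identical(fm_a$target_choice, fm_b$target_choice))
    stop("feature matrices must cover the same trials")
  break_tie_scores(score_trials(model_a, fm_a), score_trials(model_b, fm_b))
}
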