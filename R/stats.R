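#' One-sided binomial test of per-subject improvement
#'
#' The default-subset performance over `n` trials is summarized by the
#' maximum-likelihood binomial success probability `p_hat = k_default / n`.
#' The reported p-value is the probability of observing at least `k_custom`
#' correct trials under `Binomial(n, p_hat)`, computed by direct summation of
#' the probability mass function — the one-sided probability that the custom
#' subset's success count (or better) arises from default-subset performance.
#'
#' @param n number of trials.
#' @param k_default correct trials with the default subset.
#' @param k_custom correct trials with the custom subset.
#' @return a list of class `binomial_test_result`: `n`, `k_default`,
#'   `k_custom`, `p_hat`, `p_value`.
#' @export
binomial_improvement_test <- function(n, k_default, k_custom) {
  n <- as.integer(n); k_default <- as.integer(k_default)
  k_custom <- as.integer(k_custom)
  if (n < 1L) stop("n must be positive")
  if (k_default < 0L || k_default > n || k_custom < 0L || k_custom > n)
    stop("counts must lie in 0..n")
  p_hat <- k_default / n
  p_value <- sum(dbinom(seq.int(k_custom, n), n, p_hat))
  structure(list(n = n, k_default = k_default, k_custom = k_custom,
                 p_hat = p_hat, p_value = min(1, p_value)),
            class = "binomial_test_result")
}

#' @export
print.binomial_test_result <- function(x, ...) {
  cat(sprintf("<binomial_test> n=%d, default %d, custom %d: P(X >= %d | p=%.3f) = %.4g\n",
              x$n, x$k_default, x$k_custom, x$k_custom, x$p_hat, x$p_value))
  invisible(x)
}

#' Descriptive group summaries of paired subset improvements
#'
#' Aggregates per-subject calibration results by group: mean accuracy per
#' subset, mean paired improvement (custom - default) with a percentile
#' bootstrap confidence interval over subjects, and the count of subjects
#' individually significant at `alpha`. These are descriptive statistics, not
#' a mixed-model analysis; a Bonferroni-adjusted significance count is also
#' reported for user judgment.
#'
#' @param results data frame with columns `subject`, `group`, `acc_default`,
#'   `acc_custom`, and `p_value`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param alpha per-subject significance level.
#' @param conf confidence level of the percentile interval.
#' @return a data frame with one row per group and attribute
#'   `significant_subjects` (named list of subject ids per group).
#' @export
summarize_groups <- function(results, n_boot = 2000L, seed = 1L,
                             alpha = 0.05, conf = 0.95) {
  need <- c("subject", "group", "acc_default", "acc_custom", "p_value")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "))
  groups <- unique(results$group)
  sig_list <- list()
  rows <- lapply(groups, function(g) {
    d <- results[results$group == g, , drop = FALSE]
    if (nrow(d) == 0L) stop("empty group: ", g)
    imp <- d$acc_custom - d$acc_default
    ci <- with_seed(derive_seed(seed, match(g, groups)), {
      boots <- vapply(seq_len(n_boot), function(i)
        mean(imp[sample.int(length(imp), replace = TRUE)]), numeric(1))
      quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    })
    sig <- d$p_value < alpha
    sig_bonf <- d$p_value < alpha / nrow(results)
    sig_list[[g]] <<- d$subject[sig]
    data.frame(group = g, n = nrow(d),
               mean_acc_default = mean(d$acc_default),
               mean_acc_custom = mean(d$acc_custom),
               mean_improvement = mean(imp),
               ci_lower = ci[1], ci_upper = ci[2],
               n_significant = sum(sig),
               n_significant_bonferroni = sum(sig_bonf),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "significant_subjects") <- sig_list
  out
}
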