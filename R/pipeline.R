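#' Pipeline configuration
#'
#' Bundles the per-stage configurations and I/O defaults used by
#' [run_calibration_comparison()] and [run_study()].
#'
#' @param feature a [feature_config()].
#' @param swlda a [swlda_config()].
#' @param selection a [selection_config()].
#' @param max_trials trials used for the calibration comparison; sessions
#'   with more trials use the first `max_trials`.
#' @param car `"auto"` retries with a common average reference when neither
#'   subset calibrates; `"always"`/`"never"` force the choice.
#' @param n_boot,alpha group-summary settings.
#' @param seed integer seed for stochastic stages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(feature = feature_config(),
                            swlda = swlda_config(),
                            selection = selection_config(),
                            max_trials = 30L,
                            car = c("auto", "always", "never"),
                            n_boot = 2000L, alpha = 0.05, seed = 1L) {
  structure(list(feature = feature, swlda = swlda, selection = selection,
                 max_trials = as.integer(max_trials), car = match.arg(car),
                 n_boot = as.integer(n_boot), alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

as_epoch_set <- function(x) {
  if (inherits(x, "epoch_set")) x
  else if (is.character(x) && length(x) == 1L) load_session_bundle(x)
  else stop("expected an epoch_set or a bundle path")
}

#' Compare default and forward-selected custom electrode subsets
#'
#' Fits and evaluates the default-8 subset and a greedy forward-selected
#' custom subset on the same calibration trials (the first
#' `config$max_trials`), applies the flash-count tie-break, and runs the
#' one-sided binomial improvement test on the tie-broken correct counts.
#' When neither subset calibrates without spatial filtering and
#' `config$car = "auto"`, both arms are retried after a common average
#' reference; a subject for whom both arms still fail is reported as
#' non-calibrating rather than raising an error.
#'
#' @param x an [epoch_set()] or a session-bundle path.
#' @param config a [pipeline_config()].
#' @param default_subset electrode names of the comparison subset.
#' @return a list of class `calibration_comparison`: the selection result,
#'   both `subset_calibration`s, tie-break output, binomial test, settings
#'   log, and a one-row data frame `row` for cohort tables.
#' @export
run_calibration_comparison <- function(x, config = pipeline_config(),
                                       default_subset = NULL) {
  es <- as_epoch_set(x)
  if (is.null(default_subset)) default_subset <- es$montage$default8
  if (n_trials(es) > config$max_trials)
    es <- trim_trials(es, config$max_trials)
  car_used <- config$car == "always"
  if (car_used) es <- apply_car(es)
  res <- compare_once(es, config, default_subset)
  if (res$failed_both && config$car == "auto") {
    car_used <- TRUE
    res <- compare_once(apply_car(es), config, default_subset)
  }
  if (res$failed_both) {
    return(structure(list(calibrated = FALSE, car_used = car_used,
                          n_trials = n_trials(es),
                          row = data.frame(acc_default = NA_real_,
                                           acc_custom = NA_real_,
                                           r_used = NA_integer_,
                                           n = n_trials(es),
                                           p_value = NA_real_,
                                           calibrated = FALSE)),
                     class = "calibration_comparison"))
  }
  n <- res$custom$n_trials
  # an arm that cannot calibrate scores zero correct trials
  tie <- if (res$custom$failed || res$default$failed)
    list(acc_a = res$custom$accuracy, acc_b = res$default$accuracy,
         r_used = es$protocol$flashes_per_choice, tie = FALSE)
  else break_tie_scores(res$custom$scores, res$default$scores)
  k_custom <- as.integer(round(tie$acc_a * n))
  k_default <- as.integer(round(tie$acc_b * n))
  bt <- binomial_improvement_test(n, k_default, k_custom)
  structure(list(calibrated = TRUE, car_used = car_used,
                 selection = res$selection, custom = res$custom,
                 default = res$default, tie_break = tie,
                 binomial = bt, n_trials = n,
                 settings = list(decimation_factor =
                                   round(es$protocol$sample_rate /
                                           config$feature$decimation_hz),
                                 method = config$selection$method,
                                 car_used = car_used,
                                 tie_broken = !tie$tie &&
                                   tie$r_used < es$protocol$flashes_per_choice),
                 row = data.frame(acc_default = tie$acc_b,
                                  acc_custom = tie$acc_a,
                                  r_used = tie$r_used, n = n,
                                  p_value = bt$p_value, calibrated = TRUE)),
            class = "calibration_comparison")
}

compare_once <- function(es, config, default_subset) {
  fm <- extract_features(es, config$feature)
  default_cal <- calibrate_subset(fm, default_subset, config$swlda,
                                  config$selection$method,
                                  config$selection$n_folds)
  sel <- tryCatch(forward_select(fm, config$selection, config$swlda),
                  p300select_selection_failure = function(e) NULL)
  custom_cal <- if (is.null(sel)) NULL
                else calibrate_subset(fm, sel$order, config$swlda,
                                      config$selection$method,
                                      config$selection$n_folds)
  failed_both <- default_cal$failed &&
    (is.null(custom_cal) || custom_cal$failed)
  list(selection = sel, custom = custom_cal, default = default_cal,
       failed_both = failed_both)
}

trim_trials <- function(es, k) {
  es$epochs <- es$epochs[seq_len(k), , , , drop = FALSE]
  es$flashed_label <- es$flashed_label[seq_len(k), , drop = FALSE]
  es$target_choice <- es$target_choice[seq_len(k)]
  es
}

#' @export
print.calibration_comparison <- function(x, ...) {
  if (!x$calibrated) {
    cat("<calibration_comparison> subject could not calibrate\n")
    return(invisible(x))
  }
  cat(sprintf("<calibration_comparison> custom %.3f vs default %.3f at r=%d (p=%.4g)%s\n",
              x$tie_break$acc_a, x$tie_break$acc_b, x$tie_break$r_used,
              x$binomial$p_value, if (x$car_used) " [CAR]" else ""))
  invisible(x)
}

#' Run the calibration-comparison study over a cohort
#'
#' Applies [run_calibration_comparison()] to every subject of a cohort (a
#' [make_cohort()] result, entries with `epochs` or a `config` to simulate,
#' or bundle paths with a `group` label), then summarizes groups and
#' tabulates the subset-size curve (share of subjects reaching 95% of their
#' own full-subset accuracy at each size). Deterministic given the cohort
#' and `config$seed`.
#'
#' @param cohort list of subject entries.
#' @param config a [pipeline_config()].
#' @param keep_erp if `TRUE`, attach the ERP average of the first subject of
#'   each group.
#' @return a list of class `study_report`: `subjects` (data frame), `groups`
#'   ([summarize_groups()] output), `size_curve`, `non_calibrating`, and
#'   optionally `erp`.
#' @export
run_study <- function(cohort, config = pipeline_config(), keep_erp = FALSE) {
  if (length(cohort) == 0L) stop("empty cohort")
  rows <- list()
  needed <- list()
  erp <- list()
  for (i in seq_along(cohort)) {
    entry <- cohort[[i]]
    es <- if (!is.null(entry$epochs)) entry$epochs
          else if (!is.null(entry$config)) simulate_subject(entry$config)
          else as_epoch_set(entry$path)
    cmp <- run_calibration_comparison(es, config)
    row <- cmp$row
    row$subject <- entry$id %||% as.character(i)
    row$group <- entry$group %||% "all"
    rows[[i]] <- row
    if (cmp$calibrated) {
      needed[[i]] <- data.frame(group = row$group,
                                needed = subset_size_curve(cmp$selection)$electrodes_needed)
    }
    if (keep_erp && !is.null(entry$group) && is.null(erp[[entry$group]]))
      erp[[entry$group]] <- average_erp(es)
  }
  subjects <- do.call(rbind, rows)
  ok <- subjects[subjects$calibrated, , drop = FALSE]
  groups <- if (nrow(ok) > 0L)
    summarize_groups(data.frame(subject = ok$subject, group = ok$group,
                                acc_default = ok$acc_default,
                                acc_custom = ok$acc_custom,
                                p_value = ok$p_value),
                     n_boot = config$n_boot, seed = config$seed,
                     alpha = config$alpha)
    else NULL
  nd <- do.call(rbind, needed)
  M <- config$selection$M
  size_curve <- if (!is.null(nd)) {
    do.call(rbind, lapply(split(nd, nd$group), function(d)
      data.frame(group = d$group[1], size = seq_len(M),
                 share_reaching_95pct = vapply(seq_len(M), function(s)
                   mean(d$needed <= s), numeric(1)))))
  } else NULL
  structure(list(subjects = subjects, groups = groups,
                 size_curve = size_curve,
                 non_calibrating = subjects$subject[!subjects$calibrated],
                 erp = if (keep_erp) erp else NULL),
            class = "study_report")
}

#' Severe-profile parameter-recovery study
#'
#' Simulates `n_subjects` severe-atypical subjects (30-trial 256 Hz sessions
#' by default), runs leave-one-trial-out consensus selection (M = 8, full
#' 32-channel pool) per subject, and compares the consensus subset with the
#' default-8 subset: recovery of the subject's 3 strongest-weight (planted)
#' channels, tie-broken calibration accuracies, and the binomial improvement
#' test.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials trials per session.
#' @param base_seed master seed.
#' @param config a [pipeline_config()].
#' @return a list of class `recovery_study`: per-subject data frame
#'   `subjects` and the summary scalars `recovery_rate`,
#'   `mean_improvement`, `significant_fraction`.
#' @export
recovery_study <- function(n_subjects = 20L, n_trials = 30L, base_seed = 1L,
                           config = pipeline_config()) {
  cohort <- make_cohort(c(severe_atypical = n_subjects), n_trials = n_trials,
                        base_seed = base_seed)
  rows <- lapply(cohort, function(entry) {
    es <- simulate_subject(entry$config)
    fm <- extract_features(es, config$feature)
    w <- spatial_weights(entry$profile, es$montage)
    planted <- es$montage$names[order(-w)][1:3]
    sel <- consensus_select(fm, config$selection, config$swlda)
    custom <- calibrate_subset(fm, sel$chosen, config$swlda,
                               config$selection$method,
                               config$selection$n_folds)
    default <- calibrate_subset(fm, es$montage$default8, config$swlda,
                                config$selection$method,
                                config$selection$n_folds)
    n <- custom$n_trials
    # a subset that cannot calibrate scores 0 correct trials
    tie <- if (custom$failed || default$failed)
      list(acc_a = custom$accuracy, acc_b = default$accuracy,
           r_used = fm$flashes_per_choice, tie = FALSE)
    else break_tie_scores(custom$scores, default$scores)
    bt <- binomial_improvement_test(n, round(tie$acc_b * n),
                                    round(tie$acc_a * n))
    data.frame(subject = entry$id, group = entry$group,
               planted = paste(planted, collapse = " "),
               recovered = all(planted %in% sel$chosen),
               acc_default = tie$acc_b, acc_custom = tie$acc_a,
               r_used = tie$r_used, n = n, p_value = bt$p_value,
               stringsAsFactors = FALSE)
  })
  subjects <- do.call(rbind, rows)
  structure(list(subjects = subjects,
                 recovery_rate = mean(subjects$recovered),
                 mean_improvement = mean(subjects$acc_custom -
                                           subjects$acc_default),
                 significant_fraction = mean(subjects$p_value < 0.05)),
            class = "recovery_study")
}

#' Typical-profile null-control study
#'
#' Simulates `n_subjects` typical (broad-topography) subjects with 60-trial
#' 600 Hz sessions. Per subject: the calibration comparison (first 30
#' trials) yields the custom-minus-default calibration difference, and the
#' holdout generalization experiment (40 calibration / 20 testing trials,
#' consensus selection) yields the testing difference.
#'
#' @inheritParams recovery_study
#' @param n_trials trials per session (>= 60 for the holdout experiment).
#' @return a list of class `null_control_study`: per-subject data frame
#'   `subjects` and summary scalars `mean_calibration_improvement`,
#'   `mean_testing_difference`.
#' @export
null_control_study <- function(n_subjects = 20L, n_trials = 60L,
                               base_seed = 1L, config = pipeline_config()) {
  cohort <- make_cohort(c(typical = n_subjects), n_trials = n_trials,
                        base_seed = base_seed)
  rows <- lapply(seq_along(cohort), function(i) {
    entry <- cohort[[i]]
    es <- simulate_subject(entry$config)
    cmp <- run_calibration_comparison(es, config)
    gen <- generalization_experiment(es, config$selection, config$swlda,
                                     config$feature,
                                     seed = derive_seed(config$seed, i))
    data.frame(subject = entry$id,
               cal_default = cmp$tie_break$acc_b,
               cal_custom = cmp$tie_break$acc_a,
               test_default = gen$testing$default,
               test_custom = gen$testing$custom,
               stringsAsFactors = FALSE)
  })
  subjects <- do.call(rbind, rows)
  structure(list(subjects = subjects,
                 mean_calibration_improvement =
                   mean(subjects$cal_custom - subjects$cal_default),
                 mean_testing_difference =
                   mean(subjects$test_custom - subjects$test_default)),
            class = "null_control_study")
}

#' Chance-level sanity study
#'
#' Simulates noise-only subjects (all component amplitudes 0) on the
#' default-8 montage and estimates the calibration accuracy of the default-8
#' subset per subject. With no target component, trial classification is a
#' symmetric 4-way guess, so the mean accuracy should match chance (0.25).
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials trials per session.
#' @param base_seed master seed.
#' @param config a [pipeline_config()].
#' @return a list of class `chance_level_study`: per-subject accuracies,
#'   `mean_accuracy`, and its standard error `se`.
#' @export
chance_level_study <- function(n_subjects = 200L, n_trials = 30L,
                               base_seed = 1L, config = pipeline_config()) {
  mont <- standard_montage()
  mont8 <- subset_montage(mont, mont$default8)
  prof <- zero_amplitude(profile_preset("severe_atypical"))
  acc <- vapply(seq_len(n_subjects), function(i) {
    cfg <- simulation_config(prof, n_trials = n_trials,
                             protocol = protocol2(),
                             seed = derive_seed(base_seed, i),
                             montage = mont8)
    fm <- extract_features(simulate_subject(cfg), config$feature)
    calibrate_subset(fm, mont8$names, config$swlda,
                     config$selection$method,
                     config$selection$n_folds)$accuracy
  }, numeric(1))
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 se = sd(acc) / sqrt(length(acc))),
            class = "chance_level_study")
}
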