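# Shared fixtures: all sessions are generated in code at test time.

# a small montage cut from the standard cap (keeps positions and defaults)
toy_montage <- function(channels = c("C5", "C3", "Cz", "Pz")) {
  subset_montage(standard_montage(), channels)
}

# fast low-rate protocol for unit tests
toy_protocol <- function(fs = 100) {
  protocol_spec(sample_rate = fs, flash_duration_ms = 62.5,
                inter_flash_interval_ms = 93.75)
}

# single-focus profile with controllable signal-to-noise
toy_profile <- function(center = c(-0.7, 0), spread = 0.3, amp = 6,
                        noise_sd = 0, label = "toy", ...) {
  subject_profile(label = label, topography_center = center,
                  topography_spread = spread,
                  components = list(component_spec(-1, amp * 0.6, 200, 40),
                                    component_spec(+1, amp, 350, 80)),
                  noise_sd = noise_sd, pink_exponent = 1,
                  common_mode_sd = 0, artifact_rate = 0, ...)
}

toy_session <- function(n_trials = 4, channels = c("C5", "C3", "Cz", "Pz"),
                        fs = 100, seed = 1, amp = 6, noise_sd = 0,
                        center = c(-0.7, 0), spread = 0.3, ...) {
  cfg <- simulation_config(
    toy_profile(center = center, spread = spread, amp = amp,
                noise_sd = noise_sd, ...),
    n_trials = n_trials, protocol = toy_protocol(fs), seed = seed,
    montage = toy_montage(channels))
  simulate_subject(cfg)
}

# reference detrend through lm(): independent of the package's closed form
lm_detrend <- function(x) unname(stats::residuals(stats::lm(x ~ seq_along(x))))

# Reference stepwise regression built on lm()/anova() partial-F tests;
# independent of the sweep-based implementation.
naive_stepwise <- function(X, y, max_features = 60, p_enter = 0.10,
                           p_remove = 0.15, max_iter = 100) {
  incl <- integer(0)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    if (length(incl) < max_features) {
      excl <- setdiff(seq_len(ncol(X)), incl)
      if (length(excl)) {
        ps <- vapply(excl, function(j) {
          m0 <- if (length(incl)) stats::lm(y ~ X[, incl, drop = FALSE])
                else stats::lm(y ~ 1)
          m1 <- stats::lm(y ~ X[, c(incl, j), drop = FALSE])
          stats::anova(m0, m1)[2, "Pr(>F)"]
        }, numeric(1))
        if (min(ps) < p_enter) {
          incl <- c(incl, excl[which.min(ps)])
          changed <- TRUE
        }
      }
    }
    repeat {
      if (length(incl) == 0L) break
      co <- summary(stats::lm(y ~ X[, incl, drop = FALSE]))$coefficients
      pv <- co[-1, 4]
      if (max(pv) > p_remove) {
        incl <- incl[-which.max(pv)]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- stats::lm(y ~ X[, incl, drop = FALSE])
  list(included = incl, weights = unname(stats::coef(fit))[-1],
       intercept = unname(stats::coef(fit))[1])
}

# minimal feature-matrix-like list for direct SWLDA tests
raw_fm <- function(X, y) {
  list(X = X, y = y,
       feature_map = data.frame(column = seq_len(ncol(X)),
                                channel = "Z", bin = seq_len(ncol(X))),
       channels = "Z")
}
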