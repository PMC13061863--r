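#' ERP component specification
#'
#' A Gaussian temporal profile added to target epochs:
#' `polarity * amplitude * exp(-(t - latency)^2 / (2 * width^2))`.
#'
#' @param polarity `+1` or `-1`.
#' @param amplitude peak amplitude in microvolts (>= 0).
#' @param latency_ms peak latency, ms post-stimulus.
#' @param width_ms temporal standard deviation, ms.
#' @param focus optional index of the topography focus (row of the profile's
#'   `topography_center`) that carries this component; `NULL` spreads the
#'   component over all foci. Distinct component topographies are the norm
#'   in real ERPs (fronto-central N200 vs centro-parietal P300).
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(polarity, amplitude, latency_ms, width_ms,
                           focus = NULL) {
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (latency_ms <= 0) stop("latency must be positive")
  if (width_ms <= 0) stop("width must be positive")
  structure(list(polarity = polarity, amplitude = amplitude,
                 latency_ms = latency_ms, width_ms = width_ms,
                 focus = focus),
            class = "component_spec")
}

#' Generative profile for one synthetic subject
#'
#' The target response is a sum of temporal ERP components, each weighted
#' across channels by a Gaussian spatial topography (one or several foci in
#' schematic scalp coordinates). Noise is the sum of per-channel
#' `1/f^pink_exponent`-shaped noise with standard deviation `noise_sd`
#' (optionally spatially correlated between neighbouring electrodes, as
#' volume-conducted background EEG is), a shared common-mode process, and
#' rare high-amplitude movement-like transients.
#'
#' @param label profile label (`"typical"`, `"mild_atypical"`,
#'   `"severe_atypical"`, or free text).
#' @param topography_center scalp coordinates of the response maximum:
#'   a length-2 numeric, or a k x 2 matrix of response foci for multi-focal
#'   (patchy) topographies; the channel weight is the maximum over foci.
#' @param topography_spread spatial Gaussian scale (montage units, > 0).
#' @param components list of [component_spec()] added to target epochs.
#' @param noise_sd per-channel noise standard deviation, microvolts.
#' @param pink_exponent spectral slope of the noise (0 = white).
#' @param common_mode_sd shared-noise standard deviation, microvolts.
#' @param artifact_rate fraction of epochs receiving a large transient.
#' @param noise_mix_scale spatial correlation length of the background noise
#'   (montage units). Background EEG is volume-conducted, so neighbouring
#'   electrodes see strongly correlated noise; this is what makes an
#'   electrode near the response focus genuinely more useful to a
#'   multi-channel classifier than a distant one. `0` disables mixing
#'   (independent channel noise).
#' @param noise_local_frac fraction of the per-channel noise variance that is
#'   sensor-local (spatially independent).
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(label, topography_center, topography_spread,
                            components, noise_sd, pink_exponent = 1,
                            common_mode_sd = 0, artifact_rate = 0,
                            noise_mix_scale = 0.35, noise_local_frac = 0.3) {
  if (topography_spread <= 0) stop("topography_spread must be positive")
  if (noise_sd < 0 || common_mode_sd < 0) stop("noise scales must be >= 0")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must lie in [0, 1]")
  if (noise_mix_scale < 0) stop("noise_mix_scale must be >= 0")
  if (noise_local_frac < 0 || noise_local_frac > 1)
    stop("noise_local_frac must lie in [0, 1]")
  if (!is.matrix(topography_center))
    topography_center <- matrix(as.numeric(topography_center), 1L)
  if (ncol(topography_center) != 2L)
    stop("topography_center must be length-2 or a k x 2 matrix")
  structure(list(label = label,
                 topography_center = topography_center,
                 topography_spread = topography_spread,
                 components = components, noise_sd = noise_sd,
                 pink_exponent = pink_exponent,
                 common_mode_sd = common_mode_sd,
                 artifact_rate = artifact_rate,
                 noise_mix_scale = noise_mix_scale,
                 noise_local_frac = noise_local_frac),
            class = "subject_profile")
}

#' Preset subject profiles
#'
#' Three profiles emulate the qualitative group differences reported for
#' P300 BCI users: `typical` — broad centro-parietal topography covering the
#' default-8 electrodes, moderate noise, canonical N200 + P300 components;
#' `mild_atypical` — somewhat restricted, slightly lateralized topography;
#' `severe_atypical` — strongly restricted, multi-focal left-lateral
#' topography (foci at FC5, C5 and CP5, disjoint from the default-8 set),
#' one biphasic N2-P3 complex per focus with staggered latencies, elevated
#' sensor-local noise and artifact rate. No participant waveform parameters
#' are available for the populations being emulated, so all presets are
#' configuration, not ground truth; see the methods vignette for the
#' rationale behind each value.
#'
#' @param name preset name.
#' @return a [subject_profile()].
#' @export
profile_preset <- function(name = c("typical", "mild_atypical",
                                    "severe_atypical")) {
  name <- match.arg(name)
  switch(name,
    typical = subject_profile(
      label = "typical", topography_center = c(0, -0.3),
      topography_spread = 1.0,
      components = list(component_spec(-1, 3.5, 200, 40),
                        component_spec(+1, 6.0, 350, 80)),
      noise_sd = 4, pink_exponent = 1, common_mode_sd = 1,
      artifact_rate = 0.01),
    mild_atypical = subject_profile(
      label = "mild_atypical", topography_center = c(-0.3, -0.2),
      topography_spread = 0.55,
      components = list(component_spec(-1, 3.0, 200, 40),
                        component_spec(+1, 5.0, 350, 80)),
      noise_sd = 5, pink_exponent = 1, common_mode_sd = 1.5,
      artifact_rate = 0.02),
    severe_atypical = subject_profile(
      label = "severe_atypical",
      # Patchy left-lateral foci at FC5, C5 and CP5: restricted, multi-focal
      # reorganized activity, disjoint from the default-8 locations. Each
      # focus carries its own biphasic N2-P3 complex with a staggered
      # latency, emulating the variable ERP morphology and timing reported
      # for severely affected users; noise is sensor-local (artifact/EMG
      # dominated) and elevated.
      topography_center = rbind(c(-0.7, 0.3), c(-0.7, 0), c(-0.7, -0.3)),
      topography_spread = 0.12,
      components = list(component_spec(-1, 3.0, 180, 45, focus = 1),
                        component_spec(+1, 3.0, 310, 75, focus = 1),
                        component_spec(-1, 3.0, 300, 45, focus = 2),
                        component_spec(+1, 3.0, 430, 75, focus = 2),
                        component_spec(-1, 3.0, 420, 45, focus = 3),
                        component_spec(+1, 3.0, 550, 75, focus = 3)),
      noise_sd = 8, pink_exponent = 1.2, common_mode_sd = 1,
      artifact_rate = 0.05, noise_mix_scale = 0.3,
      noise_local_frac = 1))
}

#' Write or read a subject profile as JSON
#' @param profile a [subject_profile()].
#' @param path file path.
#' @return `read_profile_json` returns a [subject_profile()].
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(lapply(unclass(profile), function(x)
    if (is.list(x)) lapply(x, unclass) else x),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- lapply(seq_len(nrow(j$components)), function(i)
    do.call(component_spec, as.list(j$components[i, ])))
  subject_profile(j$label, j$topography_center, j$topography_spread, comps,
                  j$noise_sd, j$pink_exponent, j$common_mode_sd,
                  j$artifact_rate, j$noise_mix_scale, j$noise_local_frac)
}

#' Spatial channel weights of a subject profile
#'
#' Gaussian in the distance between each electrode position and the nearest
#' topography focus, normalized so the maximum weight is 1.
#'
#' @param profile a [subject_profile()].
#' @param montage a [montage()] with positions.
#' @return named numeric vector of weights in `[0, 1]`.
#' @export
spatial_weights <- function(profile, montage) {
  stopifnot(inherits(profile, "subject_profile"), inherits(montage, "montage"))
  foci <- profile$topography_center
  w <- rep(0, length(montage$names))
  for (k in seq_len(nrow(foci))) {
    d2 <- (montage$positions[, 1] - foci[k, 1])^2 +
          (montage$positions[, 2] - foci[k, 2])^2
    w <- pmax(w, exp(-d2 / (2 * profile$topography_spread^2)))
  }
  names(w) <- montage$names
  w / max(w)
}

# per-component channel weights: Gaussian from the component's focus (or the
# maximum over all foci when the component has none)
component_weights <- function(profile, montage, component) {
  foci <- profile$topography_center
  rows <- if (is.null(component$focus)) seq_len(nrow(foci))
          else component$focus
  w <- rep(0, length(montage$names))
  for (k in rows) {
    d2 <- (montage$positions[, 1] - foci[k, 1])^2 +
          (montage$positions[, 2] - foci[k, 2])^2
    w <- pmax(w, exp(-d2 / (2 * profile$topography_spread^2)))
  }
  w
}

#' Simulation configuration
#'
#' @param profile a [subject_profile()].
#' @param n_trials number of trials.
#' @param protocol a [protocol_spec()].
#' @param seed integer seed; mandatory so every session is reproducible.
#' @param montage a [montage()].
#' @param window epoch window, ms.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(profile, n_trials = 30L, protocol = protocol2(),
                              seed, montage = standard_montage(),
                              window = c(0, 1000)) {
  if (missing(seed)) stop("seed must be set explicitly")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  structure(list(profile = profile, n_trials = as.integer(n_trials),
                 protocol = protocol, seed = as.integer(seed),
                 montage = montage, window = as.numeric(window)),
            class = "simulation_config")
}

# columns of 1/f^alpha-shaped unit-variance noise (n_samples x n_series),
# built by spectral shaping of white noise; alpha = 0 returns white noise.
colored_noise <- function(n_samples, n_series, alpha) {
  if (n_series == 0L) return(matrix(0, n_samples, 0))
  w <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  if (alpha == 0) return(w)
  k <- seq_len(n_samples) - 1
  f <- pmin(k, n_samples - k)          # FFT bin frequencies (cycles/epoch)
  scale <- c(0, f[-1]^(-alpha / 2))    # suppress DC
  scale <- scale / sqrt(mean(scale^2)) # unit process variance
  Re(mvfft(mvfft(w) * scale, inverse = TRUE)) / n_samples
}

#' Simulate one synthetic calibration session
#'
#' Per trial, the four choice labels flash `flashes_per_choice` times in a
#' per-repetition shuffled order (each label flashes once before any label
#' repeats). Target epochs receive `spatial_weights * sum(component
#' Gaussians)`; all epochs receive per-channel shaped noise, a shared
#' common-mode process, and (rarely) a large movement-like transient. The
#' result is fully reproducible from the seed.
#'
#' @param cfg a [simulation_config()].
#' @return an [epoch_set()] with generator provenance.
#' @export
simulate_subject <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  pr <- cfg$protocol
  prof <- cfg$profile
  n_t <- cfg$n_trials
  n_c <- pr$n_choices
  n_f <- n_c * pr$flashes_per_choice
  n_s <- window_samples(cfg$window, pr$sample_rate)
  channels <- cfg$montage$names
  n_ch <- length(channels)
  t_ms <- cfg$window[1] + (seq_len(n_s) - 1) * 1000 / pr$sample_rate
  templates <- vapply(prof$components, function(co)
    co$polarity * co$amplitude * exp(-(t_ms - co$latency_ms)^2 /
                                       (2 * co$width_ms^2)),
    numeric(n_s))
  cweights <- vapply(prof$components, function(co)
    component_weights(prof, cfg$montage, co), numeric(n_ch))
  signal <- templates %*% t(cweights)  # n_s x n_ch target response
  mix <- noise_mixing_matrix(prof, cfg$montage)
  with_seed(cfg$seed, {
    target_choice <- sample.int(n_c, n_t, replace = TRUE)
    flashed <- t(vapply(seq_len(n_t), function(i)
      as.integer(unlist(lapply(seq_len(pr$flashes_per_choice),
                               function(b) sample.int(n_c)))),
      integer(n_f)))
    has_signal <- any(signal != 0)
    arr <- array(0, c(n_t, n_f, n_ch, n_s))
    for (tr in seq_len(n_t)) {
      # noise: sensor-local part + spatially mixed background, both shaped
      m <- if (prof$noise_sd > 0) {
        z <- colored_noise(n_s, n_f * n_ch, prof$pink_exponent)
        z <- matrix(z, n_s * n_f, n_ch)
        if (is.null(mix)) prof$noise_sd * z
        else {
          zb <- matrix(colored_noise(n_s, n_f * n_ch, prof$pink_exponent),
                       n_s * n_f, n_ch)
          prof$noise_sd * (sqrt(prof$noise_local_frac) * z +
                             sqrt(1 - prof$noise_local_frac) * zb %*% mix)
        }
      } else matrix(0, n_s * n_f, n_ch)
      if (prof$common_mode_sd > 0)
        m <- m + as.vector(prof$common_mode_sd *
                             colored_noise(n_s, n_f, prof$pink_exponent))
      m <- array(m, c(n_s, n_f, n_ch))
      if (has_signal) {
        tgt <- which(flashed[tr, ] == target_choice[tr])
        for (ch in seq_len(n_ch))
          if (any(signal[, ch] != 0))
            m[, tgt, ch] <- m[, tgt, ch] + signal[, ch]
      }
      if (prof$artifact_rate > 0) {
        art <- which(runif(n_f) < prof$artifact_rate)
        for (fl in art) {
          lat <- runif(1, cfg$window[1], cfg$window[2])
          bump <- 80 * exp(-(t_ms - lat)^2 / (2 * 60^2))
          m[, fl, ] <- m[, fl, ] + outer(bump, runif(n_ch, 0.5, 1.5))
        }
      }
      arr[tr, , , ] <- aperm(m, c(2, 3, 1))
    }
    epoch_set(arr, flashed, target_choice, cfg$montage, pr,
              window = cfg$window,
              provenance = list(generator = "p300select::simulate_subject",
                                profile = prof$label, seed = cfg$seed))
  })
}

# Spatial mixing of the background noise: row-normalized Gaussian kernel in
# electrode distance, so each channel keeps unit noise variance while
# neighbouring channels share volume-conducted background activity.
# Returns NULL when mixing is disabled (or trivial with one channel).
noise_mixing_matrix <- function(profile, montage) {
  if (profile$noise_mix_scale <= 0 || profile$noise_local_frac >= 1 ||
      length(montage$names) < 2L)
    return(NULL)
  pos <- montage$positions
  d2 <- outer(pos[, 1], pos[, 1], `-`)^2 + outer(pos[, 2], pos[, 2], `-`)^2
  K <- exp(-d2 / (2 * profile$noise_mix_scale^2))
  K / sqrt(rowSums(K^2))  # unit row norms preserve channel variance
}

#' Generate a cohort of synthetic subjects
#'
#' Per subject, the preset profile is jittered (topography center, spread,
#' component amplitudes and noise scale drawn from narrow preset-relative
#' ranges) and a per-subject seed is derived from `base_seed`, so any subset
#' of the cohort is reproducible independently. By default the sessions are
#' not materialized (a 60-trial 600 Hz 32-channel session is several hundred
#' megabytes); each element carries a `simulation_config` to pass to
#' [simulate_subject()].
#'
#' @param sizes named integer vector, e.g.
#'   `c(typical = 10, mild_atypical = 17, severe_atypical = 24)`; names must
#'   be [profile_preset()] names.
#' @param n_trials trials per session.
#' @param base_seed integer master seed.
#' @param protocols named list mapping preset name to [protocol_spec()];
#'   defaults to the 600 Hz protocol for typical/mild and the 256 Hz protocol
#'   for severe profiles.
#' @param montage a [montage()].
#' @param materialize if `TRUE`, also simulate and attach each `epochs`.
#' @return list of subject entries: `id`, `group`, `profile`, `config`, and
#'   (if materialized) `epochs`.
#' @export
make_cohort <- function(sizes, n_trials = 30L, base_seed = 1L,
                        protocols = list(typical = protocol1(),
                                         mild_atypical = protocol1(),
                                         severe_atypical = protocol2()),
                        montage = standard_montage(), materialize = FALSE) {
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("sizes must be named by preset")
  unknown <- setdiff(names(sizes), c("typical", "mild_atypical",
                                     "severe_atypical"))
  if (length(unknown)) stop("unknown preset(s): ",
                            paste(unknown, collapse = ", "))
  out <- list()
  idx <- 0L
  for (g in names(sizes)) {
    preset <- profile_preset(g)
    for (i in seq_len(sizes[[g]])) {
      idx <- idx + 1L
      seed_i <- derive_seed(base_seed, idx)
      prof <- with_seed(seed_i, jitter_profile(preset))
      cfg <- simulation_config(prof, n_trials = n_trials,
                               protocol = protocols[[g]],
                               seed = derive_seed(seed_i, 1L),
                               montage = montage)
      entry <- list(id = sprintf("%s_%02d", g, i), group = g,
                    profile = prof, config = cfg)
      if (materialize) entry$epochs <- simulate_subject(cfg)
      out[[idx]] <- entry
    }
  }
  out
}

# narrow per-subject variation around a preset (consumes RNG draws)
jitter_profile <- function(preset) {
  amp_f <- runif(1, 0.85, 1.15)
  comps <- lapply(preset$components, function(co)
    component_spec(co$polarity, co$amplitude * amp_f,
                   co$latency_ms + runif(1, -20, 20), co$width_ms,
                   focus = co$focus))
  offset <- runif(2, -0.06, 0.06)  # common shift of all foci
  subject_profile(preset$label,
                  sweep(preset$topography_center, 2, -offset),
                  preset$topography_spread * runif(1, 0.9, 1.1),
                  comps,
                  preset$noise_sd * runif(1, 0.9, 1.1),
                  preset$pink_exponent,
                  preset$common_mode_sd * runif(1, 0.9, 1.1),
                  preset$artifact_rate)
}

# profile with all component amplitudes set to zero (noise-only sessions)
zero_amplitude <- function(profile) {
  profile$components <- lapply(profile$components, function(co) {
    co$amplitude <- 0
    co
  })
  profile
}
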