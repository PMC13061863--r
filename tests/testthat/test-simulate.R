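test_that("spatial weights follow the Gaussian distance law", {
  m <- standard_montage()
  at_c5 <- toy_profile(center = unname(m$positions["C5", ]), spread = 0.3)
  w <- spatial_weights(at_c5, m)
  expect_equal(unname(w["C5"]), 1)
  expect_true(all(w <= 1 & w >= 0))
  broad <- toy_profile(center = c(0, 0), spread = 1e6)
  expect_true(all(spatial_weights(broad, m) > 0.999))
  expect_error(toy_profile(spread = 0), "positive")
})

test_that("the severe preset is restricted, lateral, and off the default-8", {
  m <- standard_montage()
  prof <- profile_preset("severe_atypical")
  w <- spatial_weights(prof, m)
  top3 <- names(sort(w, decreasing = TRUE))[1:3]
  expect_setequal(top3, c("FC5", "C5", "CP5"))
  expect_length(intersect(top3, m$default8), 0L)
  expect_lt(max(w[m$default8]), 0.2)
  # typical preset, by contrast, covers the default-8 broadly
  wt <- spatial_weights(profile_preset("typical"), m)
  expect_gt(min(wt[m$default8]), 0.5)
})

test_that("simulated sessions respect the flash paradigm", {
  es <- toy_session(n_trials = 5, noise_sd = 2, seed = 41)
  pr <- es$protocol
  is_target <- es$flashed_label == es$target_choice[row(es$flashed_label)]
  expect_true(all(rowSums(is_target) == pr$flashes_per_choice))
  expect_true(all(rowSums(!is_target) ==
                    (pr$n_choices - 1) * pr$flashes_per_choice))
  # every label flashes once before any label repeats
  for (tr in 1:5) {
    blocks <- matrix(es$flashed_label[tr, ], nrow = pr$n_choices)
    expect_true(all(apply(blocks, 2, sort) == seq_len(pr$n_choices)))
  }
})

test_that("noise-free sessions contain exactly the weighted template", {
  es <- toy_session(n_trials = 2, amp = 6, noise_sd = 0, seed = 42)
  w <- spatial_weights(toy_profile(amp = 6), es$montage)
  t_ms <- (seq_len(100) - 1) * 10
  template <- -3.6 * exp(-(t_ms - 200)^2 / (2 * 40^2)) +
    6 * exp(-(t_ms - 350)^2 / (2 * 80^2))
  is_target <- es$flashed_label == es$target_choice[row(es$flashed_label)]
  for (tr in 1:2) {
    tg <- which(is_target[tr, ])[1]
    nt <- which(!is_target[tr, ])[1]
    for (ch in seq_along(es$montage$names)) {
      expect_equal(es$epochs[tr, tg, ch, ], w[ch] * template,
                   ignore_attr = TRUE)
      expect_equal(es$epochs[tr, nt, ch, ], rep(0, 100))
    }
  }
})

test_that("sessions are reproducible from the seed", {
  a <- toy_session(n_trials = 2, noise_sd = 3, seed = 43)
  b <- toy_session(n_trials = 2, noise_sd = 3, seed = 43)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$flashed_label, b$flashed_label)
  c <- toy_session(n_trials = 2, noise_sd = 3, seed = 44)
  expect_false(identical(a$epochs, c$epochs))
})

test_that("cohorts mirror the requested group structure reproducibly", {
  sizes <- c(typical = 10, mild_atypical = 17, severe_atypical = 24)
  co <- make_cohort(sizes, base_seed = 3)
  expect_length(co, 51L)
  expect_identical(table(vapply(co, `[[`, "", "group")),
                   table(rep(names(sizes), sizes)))
  co2 <- make_cohort(sizes, base_seed = 3)
  expect_equal(co, co2)
  # severe subjects are noisier than typical ones by construction
  nsd <- vapply(co, function(e) e$profile$noise_sd, numeric(1))
  grp <- vapply(co, `[[`, "", "group")
  expect_gt(mean(nsd[grp == "severe_atypical"]), mean(nsd[grp == "typical"]))
  expect_error(make_cohort(c(unknown = 2)), "unknown preset")
  expect_error(make_cohort(c(3, 4)), "named")
})

test_that("profile JSON round-trips including focus bindings", {
  prof <- profile_preset("severe_atypical")
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_json(prof, path)
  p2 <- read_profile_json(path)
  expect_equal(p2$topography_center, prof$topography_center,
               ignore_attr = TRUE)
  expect_equal(length(p2$components), length(prof$components))
  expect_identical(vapply(p2$components, `[[`, 0, "focus"),
                   vapply(prof$components, `[[`, 0, "focus"))
  expect_equal(p2$noise_local_frac, prof$noise_local_frac)
})

test_that("shaped noise has unit variance and the requested memory", {
  set.seed(45)
  w <- p300select:::colored_noise(256, 400, 0)
  expect_equal(sd(w), 1, tolerance = 0.02)
  pk <- p300select:::colored_noise(256, 400, 1.2)
  expect_equal(sd(pk), 1, tolerance = 0.05)
  # pink noise has positive lag-1 autocorrelation, white has none
  ac_w <- mean(apply(w, 2, function(x) cor(x[-1], x[-256])))
  ac_p <- mean(apply(pk, 2, function(x) cor(x[-1], x[-256])))
  expect_lt(abs(ac_w), 0.05)
  expect_gt(ac_p, 0.3)
})
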