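test_that("epoch_set enforces the paradigm invariants", {
  es <- toy_session(n_trials = 2)
  expect_s3_class(validate_epoch_set(es), "epoch_set")

  bad <- es
  bad$flashed_label[1, 1] <- bad$flashed_label[1, 2]  # one label 11 times
  expect_error(validate_epoch_set(bad), "exactly 10 times",
               class = "p300select_schema_error")

  bad <- es
  bad$epochs <- bad$epochs[, , 1:3, , drop = FALSE]
  expect_error(validate_epoch_set(bad), "montage",
               class = "p300select_schema_error")

  bad <- es
  bad$epochs <- bad$epochs[0, , , , drop = FALSE]
  expect_error(validate_epoch_set(bad), "no trials",
               class = "p300select_schema_error")

  bad <- es
  bad$epochs <- bad$epochs[, , , 1:10, drop = FALSE]
  expect_error(validate_epoch_set(bad), "sample axis",
               class = "p300select_schema_error")
})

test_that("common average reference matches its closed form on two channels", {
  es <- toy_session(n_trials = 1, channels = c("C5", "Cz"), noise_sd = 2,
                    seed = 3)
  ref <- apply_car(es)
  a <- es$epochs[1, 1, 1, ]
  b <- es$epochs[1, 1, 2, ]
  expect_equal(ref$epochs[1, 1, 1, ], (a - b) / 2)
  expect_equal(ref$epochs[1, 1, 2, ], (b - a) / 2)
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  es <- toy_session(n_trials = 2, noise_sd = 3, seed = 4)
  ref <- apply_car(es)
  means <- apply(ref$epochs, c(1, 2, 4), mean)
  expect_lt(max(abs(means)), 1e-9)
  ref2 <- apply_car(ref)
  expect_equal(ref2$epochs, ref$epochs)
  expect_identical(dim(ref$epochs), dim(es$epochs))
  es1 <- select_channels(es, "C5")
  expect_error(apply_car(es1), "at least 2 channels")
})

test_that("select_channels reduces and reorders; rejects bad subsets", {
  es <- toy_session(n_trials = 1, noise_sd = 1, seed = 5)
  same <- select_channels(es, es$montage$names)
  expect_equal(same$epochs, es$epochs)
  sub <- select_channels(es, c("Pz", "C5"))
  expect_identical(sub$montage$names, c("Pz", "C5"))
  expect_equal(sub$epochs[, , 1, ], es$epochs[, , 4, ])
  expect_equal(sub$epochs[, , 2, ], es$epochs[, , 1, ])
  expect_error(select_channels(es, c("C5", "C5")), "duplicate")
  expect_error(select_channels(es, "XX"), "unknown")
})

test_that("average_erp recovers the planted template after detrending", {
  es <- toy_session(n_trials = 3, noise_sd = 0, seed = 6)
  erp <- average_erp(es, window = c(0, 1000))
  w <- spatial_weights(
    toy_profile(center = c(-0.7, 0), spread = 0.3, amp = 6),
    es$montage)
  t_ms <- (seq_len(100) - 1) * 10
  template <- -3.6 * exp(-(t_ms - 200)^2 / (2 * 40^2)) +
    6 * exp(-(t_ms - 350)^2 / (2 * 80^2))
  for (ch in seq_along(es$montage$names)) {
    expect_equal(erp$target[ch, ], w[ch] * lm_detrend(template),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(max(abs(erp$nontarget)), 0)
  expect_identical(erp$n_target, 30L + 0L)  # 3 trials x 10 target flashes
  expect_equal(erp$n_nontarget, 90)
})

test_that("constant epochs average to zero and window coverage is checked", {
  es <- toy_session(n_trials = 1, amp = 0, noise_sd = 0, seed = 7)
  es$epochs[] <- 5  # constant voltage everywhere
  erp <- average_erp(es)
  expect_equal(max(abs(erp$target)), 0, tolerance = 1e-12)
  expect_equal(max(abs(erp$nontarget)), 0, tolerance = 1e-12)
  expect_error(average_erp(es, window = c(0, 2000)), "not covered")
})

test_that("amplitude zero leaves non-target epochs identical to a signal run", {
  es0 <- toy_session(n_trials = 2, amp = 0, noise_sd = 2, seed = 8)
  es1 <- toy_session(n_trials = 2, amp = 6, noise_sd = 2, seed = 8)
  nt <- es0$flashed_label != es0$target_choice[row(es0$flashed_label)]
  for (tr in 1:2) for (fl in which(nt[tr, ]))
    expect_equal(es0$epochs[tr, fl, , ], es1$epochs[tr, fl, , ])
  # and target epochs differ exactly by the spatially weighted template
  tg <- which(!nt[1, ])[1]
  dif <- es1$epochs[1, tg, , ] - es0$epochs[1, tg, , ]
  w <- unname(spatial_weights(toy_profile(amp = 6), es0$montage))
  expect_equal(dif[2, ] * w[1], dif[1, ] * w[2], tolerance = 1e-6)
})
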