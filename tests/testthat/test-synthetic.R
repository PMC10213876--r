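# Synthetic Holter generator: subject sampling, RR series, beat waveforms,
# whole recordings with ground truth.

test_that("subject sampling reproduces the cohort cell distributions", {
  spec <- qti_group_presets("by_sex")

  # zero-variance cell: draws collapse to the printed means
  zspec <- spec
  zspec[c("qti_sd", "alpha_sd", "rr_sd")] <- 0
  profs <- sample_subject(zspec, "control", "male", n = 3, seed = 1)
  for (p in profs) {
    expect_equal(p$alpha_true, 0.147)
    expect_equal(p$qti_true, 390)
    expect_equal(p$beta_true, 390 - 1000 * 0.147)  # = 243
  }
  expect_equal(profs[[1]]$beta_true, 243)

  # law of large numbers against the configured control slope mean
  big <- sample_subject(qti_group_presets("by_genotype"), "control", "any",
                        n = 10000, seed = 2)
  alphas <- vapply(big, `[[`, numeric(1), "alpha_true")
  se <- 0.045 / sqrt(10000)
  expect_lt(abs(mean(alphas) - 0.168), 3 * se)

  expect_error(sample_subject(spec, "control", "unknown"), "no unique")
})

test_that("profile invariants are enforced", {
  expect_error(subject_profile(alpha_true = 1.2), "alpha_true")
  expect_error(subject_profile(rr_mean = 200), "rr_mean")
  expect_error(subject_profile(alpha_true = 0.5, qti_true = 400), "positive")
  p <- subject_profile(alpha_true = 0.2, qti_true = 420)
  expect_equal(p$alpha_true * 1000 + p$beta_true, p$qti_true)
})

test_that("RR series has the configured mean, circadian structure and bookkeeping", {
  const <- clean_profile()
  rr <- generate_rr_series(const, duration_s = 300, seed = 1)
  expect_true(all(rr == const$rr_mean))

  prof <- subject_profile(rr_mean = 828)
  rr <- generate_rr_series(prof, duration_s = 86400, seed = 3)
  expect_lt(abs(mean(rr) - 828) / 828, 0.01)
  # sum-of-intervals bookkeeping: beat count within 1% of duration/mean RR
  expect_lt(abs(length(rr) - 86400e3 / 828) / (86400e3 / 828), 0.01)
  expect_lte(sum(rr), 86400e3)
  # circadian modulation: night phase slower than day phase
  t_h <- cumsum(rr) / 3.6e6
  night <- rr[t_h > 18 & t_h < 22]
  day <- rr[t_h > 2 & t_h < 6]
  expect_gt(mean(night), mean(day) + prof$rr_circadian_amp)

  expect_error(generate_rr_series(prof, duration_s = -5), "positive")
})

test_that("synthesized beats have an exact tangent-method T end by construction", {
  for (qt in c(280, 350, 400, 520)) {
    b <- synthesize_beat(qt, qt + 400, fs_hz = 200)
    ons <- locate_qrs_onset(b)
    expect_equal(ons$onset, b$onset_idx)
    te <- locate_t_end_tangent(b, ons, mean_rr_ms = qt + 400)
    expect_equal(te$quality, "ok")
    expect_lt(abs(te$qt_ms - qt), 5)  # one sample at 200 Hz
  }
  # inverted T: same geometry with opposite polarity
  b <- synthesize_beat(400, 850, fs_hz = 200, t_amplitude = -0.3)
  te <- locate_t_end_tangent(b, locate_qrs_onset(b), mean_rr_ms = 850)
  expect_lt(abs(te$qt_ms - 400), 5)

  # no T wave -> nothing to measure
  b0 <- synthesize_beat(400, 850, fs_hz = 200, t_amplitude = 0)
  te0 <- locate_t_end_tangent(b0, locate_qrs_onset(b0), mean_rr_ms = 850)
  expect_equal(te0$quality, "no_t_wave")

  expect_error(synthesize_beat(900, 850), "smaller than rr")
  expect_error(synthesize_beat(400, 850, fs_hz = 100), "128")
})

test_that("recordings carry exact ground truth and the stated sample counts", {
  prof <- clean_profile()
  sim <- clean_recording(prof, duration_s = 120)
  expect_equal(nrow(sim$recording$signal), 120 * 200)
  expect_equal(ncol(sim$recording$signal), 2L)

  # noise-free: every ground-truth point lies exactly on the line
  tr <- sim$truth
  expect_equal(tr$qt_ms, prof$alpha_true * tr$rr_ms + prof$beta_true)
  expect_true(all(tr$t_end_s > tr$qrs_onset_s))

  # qt_noise_sd = 5: regression on ground truth recovers alpha within SE
  prof2 <- subject_profile(alpha_true = 0.25, qti_true = 460, qt_noise_sd = 5)
  sim2 <- generate_recording(prof2, duration_s = 1800, seed = 4)
  tr2 <- sim2$truth[!sim2$truth$ectopic, ]
  fit <- stats::lm(qt_ms ~ rr_ms, data = tr2)
  se <- summary(fit)$coefficients["rr_ms", "Std. Error"]
  expect_lt(abs(coef(fit)[["rr_ms"]] - 0.25), 3 * se)

  expect_error(generate_recording(prof, duration_s = 0), "positive")
  expect_error(generate_recording(prof, duration_s = 60, n_channels = 4), "2 or 3")
})

test_that("identical seeds give bit-identical recordings", {
  prof <- subject_profile()
  a <- generate_recording(prof, duration_s = 60, seed = 9)
  b <- generate_recording(prof, duration_s = 60, seed = 9)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$truth, b$truth)
  c <- generate_recording(prof, duration_s = 60, seed = 10)
  expect_false(identical(a$recording$signal, c$recording$signal))
})
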