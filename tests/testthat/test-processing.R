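# ECG processing: R-peak detection, template averaging, QRS onset,
# tangent-method T end, whole-recording measurement with validity filters.

test_that("R-peak detection matches ground truth on synthetic recordings", {
  prof <- clean_profile()
  sim <- clean_recording(prof, duration_s = 120)
  pk <- detect_r_peaks(sim)
  truth_pk <- round(sim$truth$r_peak_s * 200) + 1
  expect_equal(length(pk), nrow(sim$truth))
  expect_true(all(abs(pk - truth_pk) <= 1))

  # with default noise/jitter/ectopy: recall and precision >= 99.9%
  noisy <- noisy_fixture()
  pk <- detect_r_peaks(noisy)
  truth_pk <- round(noisy$truth$r_peak_s * 200) + 1
  d <- outer(pk, truth_pk, function(a, b) abs(a - b))
  matched <- apply(d <= 5, 2, any)
  expect_gte(mean(matched), 0.999)                      # recall
  expect_gte(mean(apply(d <= 5, 1, any)), 0.999)        # precision
  # beat-count bookkeeping: duration / realized mean RR within 1%
  expected_n <- 600e3 / mean(noisy$truth$rr_ms)
  expect_lt(abs(length(pk) - expected_n) / expected_n, 0.01)

  zero <- ecg_recording(matrix(0, 2000, 2), 200)
  expect_warning(pk0 <- detect_r_peaks(zero, channel = 1), "flat")
  expect_length(pk0, 0)
})

test_that("template averaging windows, counts and noise reduction behave", {
  # 830 ms is exactly 166 samples at 200 Hz, so every noise-free beat is
  # sampled at the same phase and the template must equal any single beat
  prof <- clean_profile(rr_mean = 830)
  sim <- clean_recording(prof, duration_s = 60)
  pk <- detect_r_peaks(sim)
  tb <- build_templates(sim, pk)
  expect_equal(length(tb$templates), 2L)   # 60 s -> 2 windows
  expect_equal(vapply(tb$templates, `[[`, 0L, "window_index"), 0:1)
  # identical noise-free beats: the template equals any single beat
  # (extracted from the raw signal on the template's own grid)
  tpl <- tb$templates[[2]]
  seg <- sim$recording$signal[pk[40] + (-(tpl$r_offset - 1)):(length(tpl$waveform) - tpl$r_offset), 1]
  expect_lt(max(abs(tpl$waveform - seg)), 1e-9)
  expect_equal(tpl$mean_rr_ms, prof$rr_mean)

  # averaging n beats reduces white noise roughly by sqrt(n): compare a
  # same-seed noisy template against its noise-free counterpart
  noisy <- generate_recording(prof, duration_s = 60, seed = 2,
                              noise_sd = 0.02, wander_amp = 0)
  clean <- generate_recording(prof, duration_s = 60, seed = 2,
                              noise_sd = 0, wander_amp = 0)
  tpl_n <- build_templates(noisy, detect_r_peaks(noisy))$templates[[2]]
  tpl_c <- build_templates(clean, detect_r_peaks(clean))$templates[[2]]
  resid <- tpl_n$waveform - tpl_c$waveform
  expect_lt(stats::sd(resid), 3 * 0.02 / sqrt(tpl_n$n_beats))
  expect_gt(stats::sd(resid), 0.2 * 0.02 / sqrt(tpl_n$n_beats))

  # windows below the beat minimum yield no template
  tb_strict <- build_templates(sim, pk, min_beats = 500)
  expect_length(tb_strict$templates, 0)
  expect_true(all(tb_strict$skipped$reason == "low_beat_count"))
})

test_that("ectopic beats are rejected before averaging", {
  prof <- subject_profile(alpha_true = 0.2, qti_true = 420, qt_noise_sd = 0,
                          rr_mean = 830, rr_circadian_amp = 0,
                          rr_short_term_sd = 0, ectopy_rate = 0.08)
  sim <- clean_recording(prof, duration_s = 240, seed = 7)
  expect_gt(sum(sim$truth$ectopic), 0)
  pk <- detect_r_peaks(sim)
  tb <- build_templates(sim, pk)
  # reference: a raw-signal segment around a normal beat away from ectopics
  normal_pk <- round(sim$truth$r_peak_s[!sim$truth$ectopic] * 200) + 1
  ref_pk <- normal_pk[10]
  tpl1 <- tb$templates[[1]]
  offs <- (-(tpl1$r_offset - 1)):(length(tpl1$waveform) - tpl1$r_offset)
  seg <- sim$recording$signal[ref_pk + offs, 1]
  # ectopics (8%) are excluded, so every averaged template stays clean
  for (tpl in tb$templates) {
    expect_lt(max(abs(tpl$waveform - seg)), 0.02)
  }
})

test_that("QRS onset is located exactly on clean templates and fails on flat ones", {
  b <- synthesize_beat(400, 850, fs_hz = 200)
  ons <- locate_qrs_onset(b)
  expect_equal(ons$onset, b$onset_idx)
  expect_equal(ons$iso, 0)

  flat <- list(waveform = numeric(400), fs_hz = 200, r_offset = 200L,
               mean_rr_ms = 800)
  expect_equal(locate_qrs_onset(flat)$quality, "onset_fail")
})

test_that("tangent T end matches the closed-form intersection on triangular T waves", {
  for (fs in c(128, 200, 250)) {
    tpl <- triangle_template(fs_hz = fs)
    te <- locate_t_end_tangent(tpl, tpl$onset_idx, mean_rr_ms = 900)
    expect_equal(te$quality, "ok")
    expect_equal(te$t_end, tpl$t_end_idx, tolerance = 1e-8)
  }
  # low-amplitude T rejected
  tiny <- triangle_template(height = 0.02)
  expect_equal(locate_t_end_tangent(tiny, tiny$onset_idx,
                                    mean_rr_ms = 900)$quality, "no_t_wave")
})

test_that("whole-recording measurement applies the validity filters", {
  prof <- subject_profile(alpha_true = 0.2, qti_true = 420, qt_noise_sd = 5)
  sim <- noisy_fixture()
  m <- measure_recording(sim, min_useful_h = 0)
  expect_equal(m$report$n_windows, 20L)            # 10 min
  expect_gte(m$report$n_ok, 19L)
  ok <- m$measurements[m$measurements$quality == "ok", ]
  expect_true(all(ok$qt_ms > 100 & ok$qt_ms <= 700))

  # RR pairing: measurement rr matches the window mean of ground-truth RR
  tr <- sim$truth[!sim$truth$ectopic, ]
  win_rr <- tapply(tr$rr_ms, floor(tr$r_peak_s / 30), mean)
  expect_lt(max(abs(ok$rr_ms - win_rr[as.character(ok$window_index)])), 10)

  # a recording shorter than the useful-registration minimum is invalid
  m3 <- measure_recording(sim)   # default 4 h rule on a 10-min recording
  expect_equal(m3$report$status, "invalid")
  expect_match(m3$report$exclusion_reason, "useful registration")

  # QT programmed above 700 ms everywhere: all templates filtered, invalid
  long_prof <- clean_profile(rr_mean = 1100)
  sim_long <- clean_recording(long_prof, duration_s = 120,
                              qt_override = 720)
  m_long <- measure_recording(sim_long, min_useful_h = 0.01)
  expect_equal(m_long$report$n_ok, 0L)
  expect_equal(m_long$report$status, "invalid")
  expect_true(any(m_long$measurements$quality == "qt_gt_700"))
})

test_that("channel selection prefers the lead with the larger T wave", {
  sim <- noisy_fixture()
  expect_equal(select_channel(sim$recording), 1L)
  flipped <- sim$recording
  flipped$signal <- flipped$signal[, 2:1]
  expect_equal(select_channel(flipped), 2L)
})
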