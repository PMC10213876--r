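# Shared fixtures, built in code. Deterministic profiles for the generator
# tests; a cached medium-length noisy recording reused across test files.

clean_profile <- function(alpha = 0.2, qti = 420, rr_mean = 828) {
  subject_profile(alpha_true = alpha, qti_true = qti, rr_mean = rr_mean,
                  qt_noise_sd = 0, rr_circadian_amp = 0,
                  rr_short_term_sd = 0, ectopy_rate = 0)
}

# generate_recording with all signal noise off
clean_recording <- function(profile, duration_s, fs_hz = 200, seed = 1, ...) {
  generate_recording(profile, duration_s = duration_s, fs_hz = fs_hz,
                     seed = seed, noise_sd = 0, wander_amp = 0, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

# 10-minute recording with default noise/jitter, shared by detection,
# template and measurement tests.
noisy_fixture <- function() {
  if (is.null(.fixture_cache$noisy)) {
    prof <- subject_profile(alpha_true = 0.2, qti_true = 420, qt_noise_sd = 5)
    .fixture_cache$noisy <- generate_recording(prof, duration_s = 600, seed = 11)
  }
  .fixture_cache$noisy
}

# Hand-built template with a triangular T wave: linear rise to an apex, then
# a linear descent reaching baseline exactly at sample `onset_idx +
# t_end_ms/dt`. The tangent of a straight limb is the limb itself, so the
# closed-form T-end is that sample exactly. The T-end locator is handed the
# onset index directly, so no QRS is needed.
triangle_template <- function(fs_hz = 200, onset_idx = 40, apex_ms = 280,
                              t_end_ms = 400, height = 0.4) {
  dt <- 1000 / fs_hz
  n <- onset_idx + round(700 / dt)
  w <- numeric(n)
  apex_idx <- onset_idx + round(apex_ms / dt)
  end_idx <- onset_idx + round(t_end_ms / dt)
  rise <- (onset_idx + round(150 / dt)):apex_idx
  w[rise] <- height * (rise - rise[1]) / (apex_idx - rise[1])
  fall <- apex_idx:end_idx
  w[fall] <- height * (end_idx - fall) / (end_idx - apex_idx)
  list(waveform = w, fs_hz = fs_hz, r_offset = onset_idx + round(40 / dt),
       mean_rr_ms = 900, window_index = 0L, window_start_s = 0,
       onset_idx = onset_idx, t_end_idx = end_idx)
}
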