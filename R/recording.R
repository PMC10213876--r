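#' Construct an ECG recording object
#'
#' Container for a multichannel ambulatory ECG: a samples x channels matrix
#' in mV with its sampling rate and start time.
#'
#' @param signal Numeric matrix, samples in rows, channels in columns (mV).
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param start_time Start-of-recording clock time, `"HH:MM:SS"`.
#' @param channel_labels Character vector of channel names.
#' @return An object of class `qti_ecg`.
#' @export
ecg_recording <- function(signal, fs_hz, start_time = "08:00:00",
                          channel_labels = NULL) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1L)
  stopifnot(is.numeric(fs_hz), fs_hz > 0)
  labels <- channel_labels %||% paste0("CH", seq_len(ncol(signal)))
  structure(
    list(signal = signal, fs_hz = fs_hz, start_time = start_time,
         channel_labels = labels),
    class = "qti_ecg"
  )
}

#' @export
print.qti_ecg <- function(x, ...) {
  n <- nrow(x$signal)
  cat(sprintf("<qti_ecg> %d channel(s) x %d samples @ %g Hz (%.2f h), start %s\n",
              ncol(x$signal), n, x$fs_hz, n / x$fs_hz / 3600, x$start_time))
  invisible(x)
}

#' Generate an annotated synthetic Holter recording
#'
#' Assembles a multichannel recording from a circadian RR series
#' ([generate_rr_series()]) and programmed beats ([synthesize_beat()]):
#' each beat's true QT follows the subject's linear QT-RR relation evaluated
#' at the preceding RR interval, `QT = alpha_true * RR_prev + beta_true +
#' N(0, qt_noise_sd^2)`. Channel 1 carries the full-amplitude signal; further
#' channels are attenuated copies with independent noise. Additive white
#' noise and slow sinusoidal baseline wander emulate recording artifact, and
#' a fraction `ectopy_rate` of beats is replaced by wide ectopic complexes
#' (no P wave, discordant repolarization) to exercise template outlier
#' rejection.
#'
#' @param profile A [subject_profile()].
#' @param duration_s Recording duration in seconds (> 0); default 24 h.
#' @param fs_hz Sampling rate in Hz (default 200).
#' @param n_channels Number of channels, 2 or 3.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   recordings.
#' @param noise_sd White-noise standard deviation per channel (mV).
#' @param wander_amp Baseline-wander amplitude (mV).
#' @param qt_override If non-`NULL`, a fixed programmed QT (ms) used for every
#'   beat instead of the subject's QT-RR relation (for filter-path tests).
#' @return A list with elements `recording` (a [ecg_recording()]) and `truth`,
#'   a data frame of per-beat ground truth with columns `beat_index`,
#'   `r_peak_s`, `qrs_onset_s`, `t_end_s`, `qt_ms`, `rr_ms` (preceding RR) and
#'   `ectopic`.
#' @examples
#' prof <- subject_profile(rr_circadian_amp = 0, rr_short_term_sd = 0,
#'                         qt_noise_sd = 0, ectopy_rate = 0)
#' rec <- generate_recording(prof, duration_s = 60, seed = 1)
#' @export
generate_recording <- function(profile, duration_s = 86400, fs_hz = 200,
                               n_channels = 2, seed = NULL,
                               noise_sd = 0.02, wander_amp = 0.05,
                               qt_override = NULL) {
  stopifnot(inherits(profile, "qti_subject"))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!n_channels %in% c(2L, 3L)) stop("n_channels must be 2 or 3")
  if (fs_hz < 128) stop("fs_hz must be >= 128")
  dt <- 1000 / fs_hz
  n_samples <- round(duration_s * fs_hz)

  with_seed(seed, {
    rr <- generate_rr_series(profile, duration_s)
    nb <- length(rr)
    # QRS onsets; first beat after a 0.5 s lead-in
    onset_ms <- 500 + c(0, cumsum(rr[-nb]))
    rr_prev <- c(profile$rr_mean, rr[-nb])
    qt <- if (is.null(qt_override)) {
      profile$alpha_true * rr_prev + profile$beta_true +
        stats::rnorm(nb, 0, profile$qt_noise_sd)
    } else {
      rep(qt_override, nb)
    }
    qt <- pmin(pmax(qt, 120), rr - 60)
    ect <- stats::runif(nb) < profile$ectopy_rate

    # drop beats whose waveform would run past the end of the signal
    fits <- onset_ms + pmax(qt, 420) <= duration_s * 1000 - dt
    base <- numeric(n_samples)
    for (k in which(fits)) {
      span_ms <- if (ect[k]) 420 else qt[k]
      i0 <- max(1L, floor((onset_ms[k] - 200) / dt) + 1L)
      i1 <- min(n_samples, ceiling((onset_ms[k] + span_ms) / dt) + 1L)
      idx <- i0:i1
      t_rel <- (idx - 1) * dt - onset_ms[k]
      base[idx] <- base[idx] +
        beat_voltage(t_rel, qt[k], profile$t_amplitude, ectopic = ect[k])
    }

    gains <- c(1, 0.7, 0.55)[seq_len(n_channels)]
    t_s <- (seq_len(n_samples) - 1) / fs_hz
    sig <- matrix(0, n_samples, n_channels)
    for (ch in seq_len(n_channels)) {
      wander <- if (wander_amp > 0) {
        ph <- stats::runif(2, 0, 2 * pi)
        wander_amp * (sin(2 * pi * 0.19 * t_s + ph[1]) +
                        0.6 * sin(2 * pi * 0.31 * t_s + ph[2]))
      } else 0
      noise <- if (noise_sd > 0) stats::rnorm(n_samples, 0, noise_sd) else 0
      sig[, ch] <- gains[ch] * base + wander + noise
    }

    # ectopic complexes are wide: their apex sits later than a normal R wave
    apex_ms <- ifelse(ect, 80, .R_APEX_MS)
    truth <- data.frame(
      beat_index = which(fits),
      r_peak_s = (onset_ms[fits] + apex_ms[fits]) / 1000,
      qrs_onset_s = onset_ms[fits] / 1000,
      t_end_s = (onset_ms[fits] + qt[fits]) / 1000,
      qt_ms = ifelse(ect[fits], NA_real_, qt[fits]),
      rr_ms = rr_prev[fits],
      ectopic = ect[fits]
    )
    list(recording = ecg_recording(sig, fs_hz),
         truth = truth,
         profile = profile)
  })
}
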