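# Beat morphology: a sum of compact-support cosine bumps (P, Q, R, S) and an
# asymmetric T wave whose terminal limb is exactly linear, reaching the
# isoelectric line (0 mV) at precisely t = qt_ms after QRS onset. A linear
# terminal limb makes the tangent-method T-end a closed-form target: the
# maximum-slope tangent of a straight limb is the limb itself, so its
# baseline intersection is the programmed QT by construction. The signal is
# identically zero outside the component supports, so QRS onset (t = 0) is a
# geometrically exact feature as well.

# Full-cycle raised-cosine bump: 0 at both ends, peak `a` at the midpoint,
# zero outside (t0, t1).
cosine_bump <- function(t, t0, t1, a) {
  v <- numeric(length(t))
  inside <- t > t0 & t < t1
  v[inside] <- a * 0.5 * (1 - cos(2 * pi * (t[inside] - t0) / (t1 - t0)))
  v
}

# QRS geometry (ms relative to QRS onset). R apex at 41 ms.
.QRS_P  <- c(-180, -80, 0.12)
.QRS_Q  <- c(0, 20, -0.10)
.QRS_R  <- c(20, 62, 1.00)
.QRS_S  <- c(62, 82, -0.18)
.QRS_END <- 82
.R_APEX_MS <- 41

# Continuous beat voltage (mV) at times t_ms relative to QRS onset.
beat_voltage <- function(t_ms, qt_ms, t_amplitude = 0.30, ectopic = FALSE,
                         with_p = TRUE) {
  if (ectopic) {
    # wide bizarre complex, no P wave, discordant repolarization
    return(cosine_bump(t_ms, 0, 160, 1.40) +
             cosine_bump(t_ms, 170, 400, -0.35))
  }
  v <- cosine_bump(t_ms, .QRS_Q[1], .QRS_Q[2], .QRS_Q[3]) +
    cosine_bump(t_ms, .QRS_R[1], .QRS_R[2], .QRS_R[3]) +
    cosine_bump(t_ms, .QRS_S[1], .QRS_S[2], .QRS_S[3])
  if (with_p) v <- v + cosine_bump(t_ms, .QRS_P[1], .QRS_P[2], .QRS_P[3])
  if (t_amplitude != 0 && qt_ms > .QRS_END + 20) {
    t_on <- max(90, 0.55 * qt_ms)
    t_apex <- t_on + 0.6 * (qt_ms - t_on)
    rise <- t_ms > t_on & t_ms <= t_apex
    fall <- t_ms > t_apex & t_ms < qt_ms
    v[rise] <- v[rise] +
      t_amplitude * 0.5 * (1 - cos(pi * (t_ms[rise] - t_on) / (t_apex - t_on)))
    v[fall] <- v[fall] +
      t_amplitude * (1 - (t_ms[fall] - t_apex) / (qt_ms - t_apex))
  }
  v
}

#' Synthesize a single ECG beat with a programmed QT interval
#'
#' Produces one sampled beat whose T wave ends, in the tangent-method sense,
#' exactly `qt_ms` after QRS onset: the terminal limb of the T wave is linear
#' and intersects the isoelectric line (the voltage at QRS onset, 0 mV here)
#' at the programmed QT. The QRS onset falls exactly on a sample.
#'
#' @param qt_ms Programmed QT interval in ms; must satisfy
#'   `100 < qt_ms < rr_ms`.
#' @param rr_ms RR interval in ms (beat length).
#' @param profile Optional [subject_profile()]; supplies `t_amplitude`.
#' @param fs_hz Sampling rate in Hz (>= 128).
#' @param t_amplitude T-wave amplitude in mV, overriding the profile.
#'   Zero yields a beat with no detectable T wave; negative values an
#'   inverted T.
#' @param lead_in_ms Baseline (and P wave) duration before QRS onset.
#' @param ectopic Generate a wide ectopic complex instead of a normal beat.
#' @return An object of class `qti_beat`: a list with `samples` (mV),
#'   `fs_hz`, `onset_idx` (1-based sample of QRS onset), `qt_ms`, `rr_ms`.
#' @examples
#' b <- synthesize_beat(400, 850, fs_hz = 200)
#' @export
synthesize_beat <- function(qt_ms, rr_ms, profile = NULL, fs_hz = 200,
                            t_amplitude = NULL, lead_in_ms = 250,
                            ectopic = FALSE) {
  if (fs_hz < 128) stop("fs_hz must be >= 128")
  if (!is.numeric(qt_ms) || qt_ms <= 100) stop("qt_ms must exceed 100 ms")
  if (qt_ms >= rr_ms) stop("qt_ms must be smaller than rr_ms")
  t_amp <- t_amplitude %||% (if (!is.null(profile)) profile$t_amplitude else 0.30)
  dt <- 1000 / fs_hz
  lead_n <- round(lead_in_ms / dt)
  n <- lead_n + ceiling(rr_ms / dt)
  t_ms <- (seq_len(n) - 1 - lead_n) * dt
  structure(
    list(samples = beat_voltage(t_ms, qt_ms, t_amp, ectopic = ectopic),
         fs_hz = fs_hz, onset_idx = lead_n + 1L,
         qt_ms = qt_ms, rr_ms = rr_ms),
    class = "qti_beat"
  )
}
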