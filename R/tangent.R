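# QRS-onset and tangent-method T-end location on averaged beat templates.
# The isoelectric reference is the voltage at QRS onset; the T-wave end is
# where the maximum-slope tangent of the T wave's terminal limb (downslope
# for upright, upslope for inverted T waves) crosses that reference.

#' Locate QRS onset on a beat template
#'
#' Finds the last quiescent sample before the first QRS deflection: starting
#' from the earliest strong-slope sample of the QRS upstroke, the algorithm
#' walks backwards to the last position where the backward difference stays
#' below a fraction of the maximum QRS slope for two consecutive samples
#' (so that stationary points inside the QRS, e.g. the Q-wave apex, are not
#' mistaken for baseline).
#'
#' @param template A `qti_template` from [build_templates()], or a
#'   `qti_beat` from [synthesize_beat()].
#' @param slope_frac Quiescence threshold as a fraction of the maximum
#'   absolute QRS slope (default 0.05).
#' @param min_qrs_amp Minimum peak-to-baseline amplitude (mV) for a template
#'   to count as containing a QRS (default 0.2).
#' @return A list with `onset` (1-based sample index), `iso` (isoelectric
#'   voltage, mV) and `quality` (`"ok"` or `"onset_fail"`).
#' @export
locate_qrs_onset <- function(template, slope_frac = 0.05, min_qrs_amp = 0.2) {
  w <- template_waveform(template)
  fs <- template$fs_hz
  dt_ms <- 1000 / fs
  r_idx <- template_r_index(template)
  amp <- max(abs(w - stats::median(w)))
  if (!is.finite(amp) || amp < min_qrs_amp) {
    return(list(onset = NA_integer_, iso = NA_real_, quality = "onset_fail"))
  }
  lo <- max(2L, r_idx - round(120 / dt_ms))
  if (lo >= r_idx) {
    return(list(onset = NA_integer_, iso = NA_real_, quality = "onset_fail"))
  }
  d <- c(0, diff(w)) / dt_ms                      # backward difference, mV/ms
  region <- lo:r_idx
  max_slope <- max(abs(d[region]))
  if (max_slope <= 0) {
    return(list(onset = NA_integer_, iso = NA_real_, quality = "onset_fail"))
  }
  thr <- slope_frac * max_slope
  strong <- region[abs(d[region]) >= 0.2 * max_slope]
  s0 <- if (length(strong)) strong[1L] else r_idx
  quiet <- abs(d) <= thr
  onset <- NA_integer_
  for (i in seq(s0 - 1L, lo, by = -1L)) {
    if (quiet[i] && quiet[i - 1L]) { onset <- i; break }
  }
  if (is.na(onset)) {
    # no quiescent run inside the search span: take its start
    onset <- lo
  }
  list(onset = onset, iso = w[onset], quality = "ok")
}

#' Locate the T-wave end by the tangent method
#'
#' Searches for the T apex between 120 ms and `min(600 ms, 0.9 * mean RR)`
#' after QRS onset, then finds the point of maximum absolute slope on the
#' terminal limb (after the apex, sloping back towards baseline) using a
#' 5-point least-squares derivative, and returns where the tangent line
#' through that point intersects the isoelectric level (the voltage at QRS
#' onset). The returned index is fractional: the intersection is solved in
#' continuous time.
#'
#' @param template A `qti_template` or `qti_beat`.
#' @param qrs_onset Result of [locate_qrs_onset()] (or an integer sample
#'   index).
#' @param min_t_amp Minimum T amplitude (mV) below which the template is
#'   flagged `no_t_wave` (default 0.05).
#' @param min_slope Minimum absolute tangent slope in mV/ms (default 0.002).
#' @param mean_rr_ms Mean RR used to bound the search window; taken from the
#'   template when available.
#' @return A list with `t_end` (fractional sample index), `qt_ms` (T-end
#'   minus onset, ms) and `quality` (`"ok"` or `"no_t_wave"`).
#' @export
locate_t_end_tangent <- function(template, qrs_onset, min_t_amp = 0.05,
                                 min_slope = 0.002, mean_rr_ms = NULL) {
  if (is.list(qrs_onset)) {
    if (identical(qrs_onset$quality, "onset_fail")) {
      return(list(t_end = NA_real_, qt_ms = NA_real_, quality = "no_t_wave"))
    }
    iso <- qrs_onset$iso
    onset <- qrs_onset$onset
  } else {
    onset <- as.integer(qrs_onset)
    iso <- template_waveform(template)[onset]
  }
  w <- template_waveform(template)
  fs <- template$fs_hz
  dt_ms <- 1000 / fs
  rr <- mean_rr_ms %||% template$mean_rr_ms %||% template$rr_ms %||% 1000
  win_lo <- onset + round(120 / dt_ms)
  win_hi <- min(length(w) - 2L, onset + round(min(600, 0.9 * rr) / dt_ms))
  # the terminal limb may run past the apex window: give it room up to
  # 780 ms so that QT values above the 700-ms validity ceiling are still
  # measured (and then filtered), rather than silently unmeasurable
  limb_hi <- min(length(w) - 2L, onset + round(min(780, 0.9 * rr) / dt_ms))
  if (win_hi - win_lo < 5L) {
    return(list(t_end = NA_real_, qt_ms = NA_real_, quality = "no_t_wave"))
  }
  v <- w - iso
  sm <- moving_average(v, 5L)
  win <- win_lo:win_hi
  apex <- win[which.max(abs(sm[win]))]
  t_sign <- sign(v[apex])
  if (abs(v[apex]) < min_t_amp || t_sign == 0) {
    return(list(t_end = NA_real_, qt_ms = NA_real_, quality = "no_t_wave"))
  }
  # 5-point least-squares (Savitzky-Golay) first derivative, mV/ms
  n <- length(v)
  d5 <- rep(NA_real_, n)
  core <- 3:(n - 2)
  d5[core] <- (2 * (v[core + 2L] - v[core - 2L]) + (v[core + 1L] - v[core - 1L])) /
    (10 * dt_ms)
  limb <- (apex + 1L):limb_hi
  if (length(limb) < 2L) {
    return(list(t_end = NA_real_, qt_ms = NA_real_, quality = "no_t_wave"))
  }
  # slope directed back towards baseline: negative for upright T, positive
  # for inverted; maximize |slope| with the correct sign
  directed <- t_sign * d5[limb]
  m_rel <- which.min(directed)
  if (!is.finite(directed[m_rel]) || directed[m_rel] >= -min_slope) {
    return(list(t_end = NA_real_, qt_ms = NA_real_, quality = "no_t_wave"))
  }
  m <- limb[m_rel]
  # The tangent line is re-estimated by least squares over a short segment
  # centred on the max-slope sample (clipped to the limb): taking the raw
  # maximum of a noisy derivative would systematically overestimate the
  # slope and shorten QT. On an exactly linear limb the refit reproduces
  # the limb itself.
  seg <- intersect(m + (-3L:3L), limb)
  if (length(seg) < 3L) seg <- m + (-1L:1L)
  t_seg <- (seg - m) * dt_ms
  cf <- stats::lm.fit(cbind(1, t_seg), v[seg])$coefficients
  slope <- cf[[2L]]
  if (!is.finite(slope) || t_sign * slope >= -min_slope) {
    return(list(t_end = NA_real_, qt_ms = NA_real_, quality = "no_t_wave"))
  }
  t_end <- m + (-cf[[1L]] / slope) / dt_ms      # fractional sample index
  if (!is.finite(t_end) || t_end > limb_hi + round(40 / dt_ms) || t_end <= onset) {
    return(list(t_end = NA_real_, qt_ms = NA_real_, quality = "no_t_wave"))
  }
  list(t_end = t_end, qt_ms = (t_end - onset) * dt_ms, quality = "ok")
}

template_waveform <- function(template) {
  template$waveform %||% template$samples
}

template_r_index <- function(template) {
  if (!is.null(template$r_offset)) return(template$r_offset)
  if (!is.null(template$onset_idx)) {
    return(template$onset_idx + round(.R_APEX_MS * template$fs_hz / 1000))
  }
  which.max(abs(template_waveform(template)))
}
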