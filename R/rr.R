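#' Generate a circadian RR-interval series
#'
#' Simulates a beat-to-beat RR sequence covering `duration_s` seconds:
#' a single 24-h sinusoid on the subject mean RR (slowest heart rate centred
#' on the configurable "night" phase) plus stationary AR(1) short-term
#' jitter. This is the simplest process that spreads QT-RR scatter points
#' across a wide span of RR intervals, which is what the downstream
#' regression needs; it does not attempt to model respiratory sinus
#' arrhythmia or heart-rate turbulence.
#'
#' @param profile A [subject_profile()].
#' @param duration_s Recording duration in seconds (> 0).
#' @param seed Optional integer seed (local to this call).
#' @param night_peak_s Seconds from recording start at which RR is longest
#'   (default 72,000 s = 20 h, i.e. 04:00 for a recording started at 08:00).
#' @param ar_phi AR(1) coefficient of the short-term jitter (0 <= phi < 1).
#' @return Numeric vector of RR intervals in ms; the cumulative sum is the
#'   last value not exceeding `duration_s * 1000`.
#' @export
generate_rr_series <- function(profile, duration_s, seed = NULL,
                               night_peak_s = 72000, ar_phi = 0.9) {
  stopifnot(inherits(profile, "qti_subject"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("duration_s must be a positive number")
  }
  rr0 <- profile$rr_mean
  amp <- profile$rr_circadian_amp
  sd_j <- profile$rr_short_term_sd
  # generous upper bound on beat count
  n <- ceiling(duration_s * 1000 / max(rr0 - amp - 3 * sd_j, 300)) + 5L
  with_seed(seed, {
    if (sd_j > 0) {
      innov <- stats::rnorm(n, 0, sd_j * sqrt(1 - ar_phi^2))
      jitter <- as.numeric(stats::filter(innov, ar_phi, method = "recursive"))
    } else {
      jitter <- numeric(n)
    }
    # circadian term evaluated on an approximate time grid, then refined once
    # (the sinusoid has a 24-h period, so one pass is ample)
    t_s <- seq_len(n) * rr0 / 1000
    for (pass in 1:2) {
      circ <- amp * cos(2 * pi * (t_s - night_peak_s) / 86400)
      rr <- pmax(rr0 + circ + jitter, 300)
      t_s <- cumsum(rr) / 1000
    }
    keep <- cumsum(rr) <= duration_s * 1000
    rr[keep]
  })
}
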