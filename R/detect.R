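#' Detect R peaks
#'
#' Amplitude-based QRS detection: the channel is high-pass filtered by
#' subtracting a 0.6-s moving average (removing baseline wander), candidate
#' local maxima of the absolute signal above an adaptive threshold are
#' collected, and a 250-ms refractory rule keeps the largest peak per beat.
#'
#' @param recording A [ecg_recording()] (or a list with a `recording` element
#'   as returned by [generate_recording()]).
#' @param channel Channel index, or `NULL` to auto-select with
#'   [select_channel()].
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based). A flat or empty channel yields `integer(0)` with a warning.
#' @export
detect_r_peaks <- function(recording, channel = NULL) {
  recording <- as_qti_ecg(recording)
  channel <- channel %||% select_channel(recording)
  x <- recording$signal[, channel]
  fs <- recording$fs_hz
  if (length(x) == 0L || max(x) - min(x) < 1e-9) {
    warning("flat or empty signal; no R peaks detected")
    return(integer(0))
  }
  y <- x - moving_average(x, round(0.6 * fs))
  ay <- abs(y)
  thr <- 0.40 * as.numeric(stats::quantile(ay, 0.9995, names = FALSE))
  if (thr <= 0) {
    warning("signal has no discernible QRS complexes")
    return(integer(0))
  }
  n <- length(ay)
  cand <- which(ay > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[ay[cand] >= ay[cand - 1L] & ay[cand] > ay[cand + 1L]]
  if (length(cand) == 0L) {
    warning("signal has no discernible QRS complexes")
    return(integer(0))
  }
  refr <- round(0.25 * fs)
  keep <- logical(length(cand))
  last <- -Inf
  last_i <- 0L
  for (i in seq_along(cand)) {
    if (cand[i] - last > refr) {
      keep[i] <- TRUE
      last <- cand[i]
      last_i <- i
    } else if (ay[cand[i]] > ay[cand[last_i]]) {
      keep[last_i] <- FALSE   # replace by the larger peak of the same beat
      keep[i] <- TRUE
      last <- cand[i]
      last_i <- i
    }
  }
  cand[keep]
}

#' Select the measurement channel
#'
#' Picks, per recording, the channel with the largest median absolute
#' T-wave-region amplitude (100-400 ms after each R peak) over a 5-minute
#' probe segment. Long-term recorders do not document which lead their QT
#' module measures; a T-amplitude criterion favours the lead on which the
#' tangent method is best conditioned.
#'
#' @param recording A [ecg_recording()].
#' @param probe_s Probe length in seconds (default 300).
#' @return Channel index (integer).
#' @export
select_channel <- function(recording, probe_s = 300) {
  recording <- as_qti_ecg(recording)
  nch <- ncol(recording$signal)
  if (nch == 1L) return(1L)
  fs <- recording$fs_hz
  n_probe <- min(nrow(recording$signal), round(probe_s * fs))
  probe <- recording$signal[seq_len(n_probe), , drop = FALSE]
  score <- vapply(seq_len(nch), function(ch) {
    sub <- ecg_recording(probe[, ch, drop = FALSE], fs)
    pk <- suppressWarnings(detect_r_peaks(sub, channel = 1L))
    if (length(pk) < 3L) return(0)
    x <- probe[, ch] - moving_average(probe[, ch], round(0.6 * fs))
    off <- round(0.100 * fs):round(0.400 * fs)
    idx <- outer(pk, off, "+")
    idx <- idx[idx <= n_probe]
    stats::median(abs(x[idx]))
  }, numeric(1))
  which.max(score)
}

as_qti_ecg <- function(x) {
  if (inherits(x, "qti_ecg")) return(x)
  if (is.list(x) && inherits(x$recording, "qti_ecg")) return(x$recording)
  stop("expected a 'qti_ecg' recording")
}
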