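#' Build 30-second averaged beat templates
#'
#' Converts a recording into one averaged beat waveform per non-overlapping
#' 30-s window, the representation from which QT is measured (a 24-h
#' recording yields up to 2,880 templates). Within each window, beats are
#' aligned on their detected R peak, compared to the window mean over a
#' +/-150 ms QRS-centred region, and beats correlating below `cor_min` are
#' excluded as ectopic/artifact before averaging. Windows retaining fewer
#' than `min_beats` beats yield no template. Each template carries the mean
#' of the accepted normal-to-normal RR intervals of its own window, the RR
#' value its QT measurement is paired with.
#'
#' @param recording A [ecg_recording()] (or `generate_recording()` output).
#' @param r_peaks Integer sample indices from [detect_r_peaks()].
#' @param window_s Window length in seconds (default 30).
#' @param channel Channel index, or `NULL` to auto-select.
#' @param min_beats Minimum accepted beats per window (default 15).
#' @param cor_min Minimum correlation with the window mean beat (default 0.9).
#' @param pre_ms,post_ms Extraction span around the R peak (ms).
#' @return A list with `templates` (list of `qti_template` objects) and
#'   `skipped` (data frame of window indices that produced no template, with
#'   a reason code).
#' @export
build_templates <- function(recording, r_peaks, window_s = 30, channel = NULL,
                            min_beats = 15, cor_min = 0.9,
                            pre_ms = 350, post_ms = 800) {
  recording <- as_qti_ecg(recording)
  channel <- channel %||% select_channel(recording)
  x <- recording$signal[, channel]
  fs <- recording$fs_hz
  n <- length(x)
  pre_n <- round(pre_ms * fs / 1000)
  post_n <- round(post_ms * fs / 1000)
  n_windows <- ceiling(n / fs / window_s)

  templates <- vector("list", n_windows)
  skipped <- list()
  if (length(r_peaks) >= 2L) {
    rr_ms <- c(NA_real_, diff(r_peaks) / fs * 1000)
  } else {
    rr_ms <- rep(NA_real_, length(r_peaks))
  }
  usable <- r_peaks - pre_n >= 1L & r_peaks + post_n <= n
  win_of <- floor((r_peaks - 1) / fs / window_s)   # 0-based
  # correlation region: +/-150 ms around the R peak
  cor_cols <- (pre_n - round(0.150 * fs)):(pre_n + round(0.150 * fs)) + 1L

  n_templates <- 0L
  for (w in seq_len(n_windows) - 1L) {
    sel <- which(win_of == w & usable)
    if (length(sel) < min_beats) {
      skipped[[length(skipped) + 1L]] <- c(w, "low_beat_count")
      next
    }
    idx <- outer(r_peaks[sel], (-pre_n):post_n, "+")
    m <- matrix(x[idx], nrow = length(sel))
    center <- colMeans(m)
    cors <- suppressWarnings(
      as.vector(stats::cor(t(m[, cor_cols, drop = FALSE]), center[cor_cols]))
    )
    keep <- !is.na(cors) & cors >= cor_min
    if (sum(keep) < min_beats) {
      skipped[[length(skipped) + 1L]] <- c(w, "low_beat_count")
      next
    }
    waveform <- colMeans(m[keep, , drop = FALSE])
    # accepted NN intervals: RR ending at a kept beat whose predecessor
    # (in the full detected sequence) was not rejected within this window
    rej <- sel[!keep]
    nn_ok <- keep & !is.na(rr_ms[sel]) & !((sel - 1L) %in% rej)
    mean_rr <- mean(rr_ms[sel][nn_ok])
    if (!is.finite(mean_rr)) {
      skipped[[length(skipped) + 1L]] <- c(w, "low_beat_count")
      next
    }
    n_templates <- n_templates + 1L
    templates[[w + 1L]] <- structure(
      list(waveform = waveform, fs_hz = fs, window_index = w,
           window_start_s = w * window_s, n_beats = sum(keep),
           mean_rr_ms = mean_rr, channel = channel,
           r_offset = pre_n + 1L),
      class = "qti_template"
    )
  }
  skipped <- if (length(skipped)) {
    data.frame(window_index = as.integer(vapply(skipped, `[`, "", 1L)),
               reason = vapply(skipped, `[`, "", 2L))
  } else {
    data.frame(window_index = integer(0), reason = character(0))
  }
  list(templates = Filter(Negate(is.null), templates),
       skipped = skipped, n_windows = n_windows, channel = channel)
}

#' @export
print.qti_template <- function(x, ...) {
  cat(sprintf("<qti_template> window %d (t = %.0f s): %d beats averaged, mean RR %.0f ms\n",
              x$window_index, x$window_start_s, x$n_beats, x$mean_rr_ms))
  invisible(x)
}
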