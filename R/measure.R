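#' Measure QT-RR points over a whole recording
#'
#' Runs the full per-recording measurement chain: R-peak detection, 30-s
#' template averaging, QRS-onset location and tangent-method T-end location,
#' producing one (QT, mean RR) point per valid window. Two validity filters
#' apply: measurements above `qt_max_ms` (default 700 ms) are flagged
#' `qt_gt_700` and excluded from regression input, and a recording whose
#' useful registration (number of ok windows times the window length) falls
#' below `min_useful_h` hours is marked invalid.
#'
#' @param recording A [ecg_recording()] or [generate_recording()] output.
#' @param channel Channel index, or `NULL` to auto-select.
#' @param window_s Template window length in seconds (default 30).
#' @param qt_max_ms Upper QT validity bound in ms (default 700).
#' @param qt_min_ms Lower QT validity bound in ms (default 100).
#' @param min_useful_h Minimum useful registration in hours (default 4).
#' @param min_beats,cor_min Passed to [build_templates()].
#' @return An object of class `qti_measure`: a list with `measurements`
#'   (data frame: `window_index`, `window_start_s`, `qt_ms`, `rr_ms`,
#'   `quality`) and `report` (list with window counts, per-quality tallies,
#'   `useful_hours`, `status` `"ok"`/`"invalid"` and the exclusion reason).
#' @export
measure_recording <- function(recording, channel = NULL, window_s = 30,
                              qt_max_ms = 700, qt_min_ms = 100,
                              min_useful_h = 4, min_beats = 15,
                              cor_min = 0.9) {
  recording <- as_qti_ecg(recording)
  channel <- channel %||% select_channel(recording)
  peaks <- suppressWarnings(detect_r_peaks(recording, channel))
  tb <- build_templates(recording, peaks, window_s = window_s,
                        channel = channel, min_beats = min_beats,
                        cor_min = cor_min)
  rows <- vector("list", length(tb$templates))
  for (i in seq_along(tb$templates)) {
    tpl <- tb$templates[[i]]
    ons <- locate_qrs_onset(tpl)
    if (ons$quality == "onset_fail") {
      rows[[i]] <- data.frame(window_index = tpl$window_index,
                              window_start_s = tpl$window_start_s,
                              qt_ms = NA_real_, rr_ms = tpl$mean_rr_ms,
                              quality = "onset_fail")
      next
    }
    te <- locate_t_end_tangent(tpl, ons)
    quality <- te$quality
    qt <- te$qt_ms
    if (quality == "ok") {
      if (qt > qt_max_ms) quality <- "qt_gt_700"
      else if (qt <= qt_min_ms) quality <- "no_t_wave"
    }
    rows[[i]] <- data.frame(window_index = tpl$window_index,
                            window_start_s = tpl$window_start_s,
                            qt_ms = qt, rr_ms = tpl$mean_rr_ms,
                            quality = quality)
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window_index = integer(0), window_start_s = numeric(0),
               qt_ms = numeric(0), rr_ms = numeric(0), quality = character(0))
  if (nrow(tb$skipped)) {
    meas <- rbind(meas, data.frame(window_index = tb$skipped$window_index,
                                   window_start_s = tb$skipped$window_index * window_s,
                                   qt_ms = NA_real_, rr_ms = NA_real_,
                                   quality = tb$skipped$reason))
  }
  meas <- meas[order(meas$window_index), , drop = FALSE]
  rownames(meas) <- NULL

  n_ok <- sum(meas$quality == "ok")
  useful_h <- n_ok * window_s / 3600
  status <- if (useful_h >= min_useful_h) "ok" else "invalid"
  report <- list(
    n_windows = tb$n_windows,
    n_templates = length(tb$templates),
    n_ok = n_ok,
    quality_counts = table(meas$quality),
    useful_hours = useful_h,
    min_useful_h = min_useful_h,
    channel = channel,
    n_beats_detected = length(peaks),
    status = status,
    exclusion_reason = if (status == "invalid")
      sprintf("less than %g h of useful registration (%.2f h)",
              min_useful_h, useful_h) else NA_character_
  )
  structure(list(measurements = meas, report = report), class = "qti_measure")
}

#' @export
print.qti_measure <- function(x, ...) {
  r <- x$report
  cat(sprintf("<qti_measure> %d/%d windows ok (%.2f h useful), status: %s\n",
              r$n_ok, r$n_windows, r$useful_hours, r$status))
  if (r$status == "invalid") cat("  ", r$exclusion_reason, "\n", sep = "")
  qc <- r$quality_counts
  if (length(qc)) {
    cat("  quality: ", paste(sprintf("%s=%d", names(qc), as.integer(qc)),
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
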