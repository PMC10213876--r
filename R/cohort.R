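#' Simulate a cohort of subject-level QTi and slope values
#'
#' Draws a whole cohort from a cohort specification (by default the
#' sex-stratified published preset): per cell, `n` subjects' true QTi and
#' QT-RR slope are sampled from the cell's normal distributions. This is the
#' distribution-level generator used for diagnostic calibration (ROC/AUC,
#' cut-offs); [run_qti_pipeline()] is the signal-level counterpart that also
#' synthesizes and measures recordings.
#'
#' @param spec A `qti_cohort_spec` (default [qti_group_presets()]`("by_sex")`).
#' @param n_per_cell Optional integer overriding every cell's `n` (useful
#'   for scaled-down property tests).
#' @param seed Optional integer seed.
#' @return A data frame of class `qti_cohort` with columns `subject_id`,
#'   `label` (`"control"`/`"LQTS"`), `subtype`, `sex`, `qti_1000` (ms) and
#'   `alpha`.
#' @examples
#' coh <- simulate_qti_cohort(seed = 1)
#' table(coh$label, coh$sex)
#' @export
simulate_qti_cohort <- function(spec = qti_group_presets("by_sex"),
                                n_per_cell = NULL, seed = NULL) {
  if (!inherits(spec, "qti_cohort_spec")) spec <- cohort_spec(spec)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      cell <- spec[i, ]
      n <- n_per_cell %||% cell$n
      if (n == 0L) return(NULL)
      qti <- stats::rnorm(n, cell$qti_mean, cell$qti_sd)
      alpha <- stats::rnorm(n, cell$alpha_mean, cell$alpha_sd)
      is_case <- cell$group != "control"
      data.frame(
        subject_id = sprintf("%s_%s_%03d", cell$group, cell$sex, seq_len(n)),
        label = if (is_case) "LQTS" else "control",
        subtype = if (is_case && cell$group != "LQTS") cell$group else "none",
        sex = cell$sex,
        qti_1000 = qti,
        alpha = alpha,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("qti_cohort", "data.frame")
    out
  })
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end pipeline with their
#' defaults: 30-s template windows, the 700-ms QT validity ceiling, the 4-h
#' useful-registration rule, the RR evaluation grid (600-1,400 ms in steps
#' of 100) and the sex-specific QTi cut-offs (430 ms male / 445 ms female).
#'
#' @param fs_hz Sampling rate (Hz).
#' @param window_s Template window (s).
#' @param qt_max_ms QT validity ceiling (ms).
#' @param min_useful_h Minimum useful registration (h).
#' @param min_points Minimum ok points for the regression.
#' @param min_beats Minimum accepted beats per template window.
#' @param qti_rr_grid RR intervals (ms) at which QT is also evaluated.
#' @param cutoffs Named per-sex QTi cut-offs (ms).
#' @param duration_s Recording duration (s).
#' @param n_channels Channels per recording (2 or 3).
#' @param seed Optional integer master seed.
#' @return A list of class `qti_config`.
#' @export
pipeline_config <- function(fs_hz = 200, window_s = 30, qt_max_ms = 700,
                            min_useful_h = 4, min_points = 480,
                            min_beats = 15,
                            qti_rr_grid = c(seq(600, 900, 100), 1000,
                                            seq(1100, 1400, 100)),
                            cutoffs = c(male = 430, female = 445),
                            duration_s = 86400, n_channels = 2,
                            seed = NULL) {
  stopifnot(window_s > 0, qt_max_ms > 0, all(qti_rr_grid > 0))
  structure(
    list(fs_hz = fs_hz, window_s = window_s, qt_max_ms = qt_max_ms,
         min_useful_h = min_useful_h, min_points = min_points,
         min_beats = min_beats, qti_rr_grid = qti_rr_grid,
         cutoffs = cutoffs, duration_s = duration_s,
         n_channels = n_channels, seed = seed),
    class = "qti_config"
  )
}

#' Run the full simulate-measure-fit-evaluate pipeline
#'
#' For each subject profile: synthesize a recording, measure QT-RR points,
#' fit the individualized regression and collect QTi, slope and Pearson r;
#' then, if both classes are present among valid subjects, evaluate the
#' cohort (ROC/AUC and metrics at the configured sex-specific cut-offs).
#' Subjects whose recording fails the useful-registration rule (or whose fit
#' fails) are excluded with a machine-readable reason, mirroring
#' per-recording exclusion accounting. Deterministic given `config$seed`.
#'
#' @param profiles List of [subject_profile()] objects (optionally with a
#'   `label` attribute; otherwise `group` `"control"` vs. anything else
#'   decides case status).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the cohort table, the
#'   metrics and a manifest are written as CSV/JSON files.
#' @param durations_s Optional per-subject recording durations (s), recycled
#'   over subjects; defaults to `config$duration_s` for everyone.
#' @return A list of class `qti_pipeline` with `cohort` (per-subject data
#'   frame including the QT grid evaluations), `excluded` (data frame of
#'   subject_id + reason), `diagnostics` (list with `roc` and per-sex
#'   metrics, or `NULL`) and `manifest`.
#' @export
run_qti_pipeline <- function(profiles, config = pipeline_config(),
                             out_dir = NULL, durations_s = NULL) {
  stopifnot(inherits(config, "qti_config"))
  if (inherits(profiles, "qti_subject")) profiles <- list(profiles)
  durations <- rep_len(durations_s %||% config$duration_s, length(profiles))
  rows <- list()
  excluded <- list()
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    sim <- generate_recording(prof, duration_s = durations[i],
                              fs_hz = config$fs_hz,
                              n_channels = config$n_channels,
                              seed = child_seed(config$seed, i))
    res <- subject_qti(sim, min_points = config$min_points,
                       window_s = config$window_s,
                       qt_max_ms = config$qt_max_ms,
                       min_useful_h = config$min_useful_h,
                       min_beats = config$min_beats)
    if (res$status != "ok") {
      reason <- if (res$status == "invalid_recording")
        res$measure$report$exclusion_reason else res$status
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = prof$subject_id, reason = reason)
      next
    }
    grid <- qti_at(res$fit, config$qti_rr_grid)
    grid_df <- as.data.frame(as.list(as.numeric(grid)))
    names(grid_df) <- paste0("qt_rr", config$qti_rr_grid)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject_id = prof$subject_id,
                 label = if (prof$group == "control") "control" else "LQTS",
                 subtype = if (prof$group %in% c("LQT1", "LQT2", "LQT3"))
                   prof$group else "none",
                 sex = prof$sex,
                 qti_1000 = res$fit$qti_1000,
                 alpha = res$fit$alpha,
                 pearson_r = res$fit$pearson_r,
                 n_points = res$fit$n_points,
                 rr_min = res$fit$rr_range[1],
                 rr_max = res$fit$rr_range[2],
                 stringsAsFactors = FALSE),
      grid_df)
  }
  cohort <- if (length(rows)) do.call(rbind, rows) else NULL
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(subject_id = character(0), reason = character(0))

  diagnostics <- NULL
  if (!is.null(cohort)) {
    pos <- as_label(cohort$label)
    if (any(pos) && !all(pos)) {
      diagnostics <- list(roc = roc_auc(cohort$qti_1000, cohort$label),
                          metrics = classify_by_sex_safe(cohort, config$cutoffs))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("qtiholter")),
    n_subjects = length(profiles),
    n_included = if (is.null(cohort)) 0L else nrow(cohort),
    n_excluded = nrow(excluded),
    seed = config$seed,
    config = unclass(config)
  )
  out <- structure(list(cohort = cohort, excluded = excluded,
                        diagnostics = diagnostics, manifest = manifest),
                   class = "qti_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# classify_by_sex needs both classes within each sex; fall back gracefully
# on small demo cohorts.
classify_by_sex_safe <- function(cohort, cutoffs) {
  tryCatch(classify_by_sex(cohort, cutoffs), error = function(e) NULL)
}

write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(x$cohort)) {
    utils::write.csv(x$cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(x$excluded, file.path(out_dir, "excluded.csv"),
                   row.names = FALSE)
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(x$diagnostics)) {
    m <- x$diagnostics$metrics
    if (!is.null(m)) {
      df <- do.call(rbind, lapply(names(m), function(nm) {
        d <- m[[nm]]
        data.frame(stratum = nm, cutoff = d$cutoff,
                   sensitivity = d$sensitivity, specificity = d$specificity,
                   accuracy = d$accuracy, lr_pos = d$lr_pos,
                   lr_neg = d$lr_neg, n = d$n)
      }))
      utils::write.csv(df, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.qti_pipeline <- function(x, ...) {
  cat(sprintf("<qti_pipeline> %d subjects: %d included, %d excluded\n",
              x$manifest$n_subjects, x$manifest$n_included,
              x$manifest$n_excluded))
  if (nrow(x$excluded)) {
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf("  excluded %s: %s\n", x$excluded$subject_id[i],
                  x$excluded$reason[i]))
    }
  }
  if (!is.null(x$diagnostics)) print(x$diagnostics$roc)
  invisible(x)
}
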