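#' Published cohort parameter presets
#'
#' Group-level distributions of the individualized QT interval (QTi, ms), the
#' QT-RR slope (dimensionless) and the mean RR interval (ms), as reported for
#' large Holter cohorts of long-QT-syndrome (LQTS) patients and healthy
#' controls. Two presets are available:
#'
#' * `"by_sex"`: controls vs. pooled LQTS, stratified by sex. This is the
#'   stratification used to derive gender-specific QTi cut-offs (430 ms in
#'   males, 445 ms in females).
#' * `"by_genotype"`: controls vs. the LQT1/LQT2/LQT3 genotypes, sexes pooled.
#'
#' Each row is one cohort cell: a (group, sex) combination with its sample
#' size and the normal-distribution parameters used by [sample_subject()] to
#' draw subject-level ground truth.
#'
#' @param preset Which stratification to return.
#' @return A `qti_cohort_spec`: a data frame with columns `group`, `sex`, `n`,
#'   `qti_mean`, `qti_sd`, `alpha_mean`, `alpha_sd`, `rr_mean`, `rr_sd`.
#' @seealso [cohort_spec()] to build a custom specification,
#'   [sample_subject()], [simulate_qti_cohort()].
#' @examples
#' qti_group_presets("by_sex")
#' @export
qti_group_presets <- function(preset = c("by_sex", "by_genotype")) {
  preset <- match.arg(preset)
  cells <- switch(preset,
    by_sex = data.frame(
      group      = c("control", "LQTS", "control", "LQTS"),
      sex        = c("male", "male", "female", "female"),
      n          = c(102L, 115L, 99L, 139L),
      qti_mean   = c(390, 465, 409, 475),
      qti_sd     = c(19, 36, 21, 34),
      alpha_mean = c(0.147, 0.212, 0.189, 0.220),
      alpha_sd   = c(0.031, 0.093, 0.048, 0.088),
      rr_mean    = c(845, 906, 810, 864),
      rr_sd      = c(105, 146, 113, 137),
      stringsAsFactors = FALSE
    ),
    by_genotype = data.frame(
      group      = c("control", "LQT1", "LQT2", "LQT3"),
      sex        = c("any", "any", "any", "any"),
      n          = c(201L, 163L, 78L, 13L),
      qti_mean   = c(399, 460, 486, 497),
      qti_sd     = c(22, 31, 35, 44),
      alpha_mean = c(0.168, 0.180, 0.276, 0.315),
      alpha_sd   = c(0.045, 0.073, 0.083, 0.069),
      rr_mean    = c(828, 884, 882, 880),
      rr_sd      = c(110, 135, 161, 116),
      stringsAsFactors = FALSE
    )
  )
  cohort_spec(cells)
}

#' Build a cohort specification
#'
#' Validates a table of cohort cells for the synthetic generator. Each cell
#' gives normal-distribution parameters for the subject-level QTi (ms), QT-RR
#' slope and mean RR interval (ms), plus a sample size.
#'
#' @param cells Data frame with columns `group`, `sex`, `n`, `qti_mean`,
#'   `qti_sd`, `alpha_mean`, `alpha_sd`, `rr_mean`, `rr_sd`.
#' @return The validated data frame with class `qti_cohort_spec`.
#' @export
cohort_spec <- function(cells) {
  needed <- c("group", "sex", "n", "qti_mean", "qti_sd",
              "alpha_mean", "alpha_sd", "rr_mean", "rr_sd")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    stop("cohort spec is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(cells$n < 0)) stop("cell counts must be >= 0")
  if (any(cells[c("qti_sd", "alpha_sd", "rr_sd")] < 0)) {
    stop("cell standard deviations must be >= 0")
  }
  if (any(cells$rr_mean < 400 | cells$rr_mean > 1500)) {
    stop("cell rr_mean must lie in [400, 1500] ms")
  }
  class(cells) <- c("qti_cohort_spec", "data.frame")
  cells
}

#' Construct a synthetic subject profile
#'
#' A subject profile holds the ground-truth QT-RR relation
#' `QT = alpha_true * RR + beta_true + noise` together with the rhythm and
#' morphology parameters the waveform generator needs. `beta_true` is never
#' set directly: it is derived from the subject's true QTi at RR = 1,000 ms
#' as `beta = QTi - 1000 * alpha`, because cohort tables parameterize QTi,
#' not the intercept.
#'
#' @param subject_id Character label.
#' @param group One of `"control"`, `"LQTS"`, `"LQT1"`, `"LQT2"`, `"LQT3"`.
#' @param sex `"male"`, `"female"` or `"any"`.
#' @param alpha_true Dimensionless QT-RR slope, in `[0, 1)`.
#' @param qti_true True QTi in ms (QT at RR = 1,000 ms).
#' @param qt_noise_sd Beat-level QT scatter around the linear relation (ms).
#' @param rr_mean Subject mean RR interval (ms), in `[400, 1500]`.
#' @param rr_circadian_amp Amplitude of the 24-h sinusoidal RR modulation (ms).
#' @param rr_short_term_sd Standard deviation of short-term AR(1) RR jitter (ms).
#' @param ectopy_rate Fraction of beats replaced by wide ectopic complexes.
#' @param t_amplitude T-wave amplitude (mV); negative values give inverted T waves.
#' @return An object of class `qti_subject`, a list with the above fields plus
#'   `beta_true` (ms).
#' @export
subject_profile <- function(subject_id = "S1",
                            group = "control",
                            sex = "any",
                            alpha_true = 0.168,
                            qti_true = 399,
                            qt_noise_sd = 6,
                            rr_mean = 828,
                            rr_circadian_amp = 80,
                            rr_short_term_sd = 40,
                            ectopy_rate = 0.002,
                            t_amplitude = 0.30) {
  stopifnot(alpha_true >= 0, alpha_true < 1,
            rr_mean >= 400, rr_mean <= 1500,
            qt_noise_sd >= 0, rr_circadian_amp >= 0, rr_short_term_sd >= 0,
            ectopy_rate >= 0, ectopy_rate < 1)
  beta_true <- qti_true - 1000 * alpha_true
  if (!is.finite(beta_true) || beta_true <= 0) {
    stop("implied intercept beta = qti_true - 1000*alpha_true must be positive")
  }
  structure(
    list(subject_id = subject_id, group = group, sex = sex,
         alpha_true = alpha_true, beta_true = beta_true, qti_true = qti_true,
         qt_noise_sd = qt_noise_sd, rr_mean = rr_mean,
         rr_circadian_amp = rr_circadian_amp,
         rr_short_term_sd = rr_short_term_sd,
         ectopy_rate = ectopy_rate, t_amplitude = t_amplitude),
    class = "qti_subject"
  )
}

#' @export
print.qti_subject <- function(x, ...) {
  cat(sprintf("<qti_subject> %s (%s, %s)\n", x$subject_id, x$group, x$sex))
  cat(sprintf("  QT = %.3f * RR + %.1f  (QTi = %.1f ms, noise sd %.1f ms)\n",
              x$alpha_true, x$beta_true, x$qti_true, x$qt_noise_sd))
  cat(sprintf("  RR mean %.0f ms, circadian amp %.0f ms, jitter sd %.0f ms, ectopy %.2f%%\n",
              x$rr_mean, x$rr_circadian_amp, x$rr_short_term_sd, 100 * x$ectopy_rate))
  invisible(x)
}

#' Draw subject profiles from a cohort cell
#'
#' Samples `n` subjects from the normal distributions of a (group, sex) cell
#' of a cohort specification: `alpha_true ~ N(alpha_mean, alpha_sd^2)`,
#' `QTi_true ~ N(qti_mean, qti_sd^2)`, `rr_mean ~ N(rr_mean, rr_sd^2)`.
#' The intercept is derived as `beta = QTi - 1000 * alpha`. Draws are clipped
#' to the profile invariants (`alpha` in `[0, 1)` with positive implied
#' intercept, `rr_mean` in `[400, 1500]` ms); with the published presets the
#' clips are essentially never active.
#'
#' @param spec A `qti_cohort_spec`, e.g. from [qti_group_presets()].
#' @param group,sex Cell selector; must match one row of `spec`.
#' @param n Number of subjects to draw.
#' @param seed Optional integer seed (local to this call).
#' @param ... Further arguments passed to [subject_profile()] (noise, rhythm
#'   and morphology parameters shared by all drawn subjects).
#' @return A single `qti_subject` if `n = 1`, otherwise a list of them.
#' @examples
#' spec <- qti_group_presets("by_sex")
#' sample_subject(spec, "control", "male", seed = 1)
#' @export
sample_subject <- function(spec, group, sex = "any", n = 1L, seed = NULL, ...) {
  if (!inherits(spec, "qti_cohort_spec")) spec <- cohort_spec(spec)
  row <- spec[spec$group == group & spec$sex == sex, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("no unique cohort cell for group='%s', sex='%s'", group, sex))
  }
  with_seed(seed, {
    alpha <- stats::rnorm(n, row$alpha_mean, row$alpha_sd)
    qti <- stats::rnorm(n, row$qti_mean, row$qti_sd)
    rrm <- stats::rnorm(n, row$rr_mean, row$rr_sd)
    alpha <- pmin(pmax(alpha, 0), (qti - 50) / 1000, 0.999)
    rrm <- pmin(pmax(rrm, 400), 1500)
    out <- lapply(seq_len(n), function(i) {
      subject_profile(subject_id = sprintf("%s_%s_%03d", group, sex, i),
                      group = group, sex = sex,
                      alpha_true = alpha[i], qti_true = qti[i],
                      rr_mean = rrm[i], ...)
    })
    if (n == 1L) out[[1L]] else out
  })
}
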