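# Cohort-level diagnostic evaluation: empirical ROC curves, the midrank
# (Mann-Whitney) AUC with DeLong variance, comparison of correlated AUCs,
# Youden cut-offs and 2x2 classification metrics. Positivity convention
# throughout: score >= cutoff is test-positive ("above is abnormal").

as_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  l <- as.character(labels)
  pos_names <- c("LQTS", "LQT1", "LQT2", "LQT3", "case", "positive", "1", "TRUE")
  l %in% pos_names
}

# Midrank AUC: P(score_pos > score_neg) + 0.5 * P(tie).
auc_midrank <- function(scores, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half); and symmetrically for negatives.
delong_placements <- function(scores, pos) {
  xs <- scores[pos]
  ys <- scores[!pos]
  n1 <- length(xs)
  n0 <- length(ys)
  r_all <- rank(c(xs, ys), ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rank(xs, ties.method = "average")) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(ys, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve with midrank AUC and DeLong confidence interval
#'
#' Builds the empirical ROC over all distinct score thresholds (positivity:
#' score >= threshold), estimates the area under the curve by the
#' Mann-Whitney midrank statistic (ties get half credit) and its variance by
#' the DeLong placement method, from which a normal-approximation confidence
#' interval is derived.
#'
#' @param scores Numeric per-subject statistic (e.g. QTi in ms).
#' @param labels Class labels; `TRUE`/case/LQTS-like values are positive.
#' @param conf_level Confidence level for the AUC interval (default 0.95).
#' @return An object of class `qti_roc`: a list with `auc`, `auc_var`,
#'   `auc_ci`, `roc` (data frame `threshold`, `sensitivity`, `specificity`),
#'   `n_pos`, `n_neg`, and the input `scores`/`labels`.
#' @examples
#' roc <- roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' roc$auc
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  pos <- as_label(labels)
  keep <- is.finite(scores) & !is.na(pos)
  scores <- scores[keep]
  pos <- pos[keep]
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pl <- delong_placements(scores, pos)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  structure(
    list(auc = pl$auc, auc_var = v, auc_ci = ci, conf_level = conf_level,
         roc = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec),
         n_pos = n1, n_neg = n0, scores = scores, labels = pos),
    class = "qti_roc"
  )
}

#' @export
print.qti_roc <- function(x, ...) {
  cat(sprintf("<qti_roc> AUC %.3f (%.0f%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, 100 * x$conf_level, x$auc_ci[1], x$auc_ci[2],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.qti_roc <- function(x, ...) {
  graphics::plot(1 - x$roc$specificity, x$roc$sensitivity, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  graphics::mtext(sprintf("AUC = %.3f", x$auc), cex = 0.8)
  invisible(x)
}

#' Optimal cut-off by the Youden index
#'
#' Returns the threshold maximizing sensitivity + specificity - 1 on the
#' empirical ROC; ties are broken towards the lower threshold.
#'
#' @param roc A `qti_roc` from [roc_auc()].
#' @return The optimal threshold (same units as the scores).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "qti_roc"))
  j <- roc$roc$sensitivity + roc$roc$specificity - 1
  roc$roc$threshold[which.max(j)]   # which.max returns the first (lowest) tie
}

#' Classification metrics at a fixed cut-off
#'
#' Applies the rule "score >= cutoff is test-positive" and reports the
#' standard 2x2 metrics: sensitivity, specificity, accuracy and the positive
#' and negative likelihood ratios (LR+ = sens/(1-spec), LR- = (1-sens)/spec).
#'
#' @param scores Numeric per-subject statistic.
#' @param labels Class labels (cases positive).
#' @param cutoff Decision threshold.
#' @return An object of class `qti_diag`: a list with `cutoff`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `accuracy`, `lr_pos`,
#'   `lr_neg`, `n`.
#' @examples
#' classify_metrics(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), cutoff = 2.5)
#' @export
classify_metrics <- function(scores, labels, cutoff) {
  pos <- as_label(labels)
  keep <- is.finite(scores) & !is.na(pos)
  scores <- scores[keep]
  pos <- pos[keep]
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (cutoff < min(scores) || cutoff > max(scores)) {
    warning("cutoff lies outside the observed score range")
  }
  test_pos <- scores >= cutoff
  tp <- sum(test_pos & pos)
  fp <- sum(test_pos & !pos)
  tn <- sum(!test_pos & !pos)
  fn <- sum(!test_pos & pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(
    list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / length(scores),
         lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
         lr_neg = if (spec > 0) (1 - sens) / spec else Inf,
         n = length(scores)),
    class = "qti_diag"
  )
}

#' @export
print.qti_diag <- function(x, ...) {
  cat(sprintf("<qti_diag> cutoff %.4g: Sens %.0f%%, Spec %.0f%%, Acc %.0f%%, +LR %.3g, -LR %.3g (n = %d)\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy, x$lr_pos, x$lr_neg, x$n))
  invisible(x)
}

#' Gender-specific QTi classification
#'
#' Applies sex-specific QTi cut-offs (default 430 ms in males, 445 ms in
#' females) to a cohort and reports metrics per sex and pooled.
#'
#' @param cohort Data frame with columns `qti_1000`, `label` and `sex`.
#' @param cutoffs Named numeric vector of per-sex cut-offs (ms).
#' @return A list of `qti_diag` objects: one per sex plus `pooled` (pooled
#'   counts with each subject classified at their own sex's cut-off).
#' @export
classify_by_sex <- function(cohort, cutoffs = c(male = 430, female = 445)) {
  stopifnot(all(c("qti_1000", "label", "sex") %in% names(cohort)))
  out <- list()
  shifted <- numeric(nrow(cohort))
  for (s in names(cutoffs)) {
    sel <- cohort$sex == s
    if (any(sel)) {
      out[[s]] <- classify_metrics(cohort$qti_1000[sel], cohort$label[sel],
                                   cutoffs[[s]])
    }
    # shift scores so one pooled cutoff of 0 reproduces per-sex decisions
    shifted[sel] <- cohort$qti_1000[sel] - cutoffs[[s]]
  }
  out$pooled <- classify_metrics(shifted, cohort$label, 0)
  out$pooled$cutoff <- NA_real_
  out
}

#' Specificity and sensitivity of QT-RR slope thresholds
#'
#' Classifies subjects by the rule "QT-RR slope >= cutoff is test-positive"
#' for each cutoff (default 0.25 and 0.30), delegating to
#' [classify_metrics()] on the slope statistic.
#'
#' @param alpha Numeric vector of per-subject QT-RR slopes.
#' @param labels Class labels (cases positive).
#' @param slope_cutoffs Numeric vector of slope thresholds.
#' @return Named list of `qti_diag` objects, one per cutoff.
#' @export
slope_threshold_metrics <- function(alpha, labels,
                                    slope_cutoffs = c(0.25, 0.30)) {
  out <- lapply(slope_cutoffs, function(ct)
    suppressWarnings(classify_metrics(alpha, labels, ct)))
  names(out) <- format(slope_cutoffs)
  out
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two diagnostic scores measured on the same subjects,
#' using the DeLong placement-value covariance of the paired midrank AUCs
#' and a two-sided z test.
#'
#' @param scores_a,scores_b Paired numeric scores on identical subjects.
#' @param labels Class labels (cases positive), shared by both scores.
#' @return An object of class `htest` with the two AUCs as `estimate`, the
#'   z statistic and the two-sided p-value. Comparing a score with itself
#'   gives z = 0, p = 1.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length")
  }
  pos <- as_label(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vcv <- s10 / n1 + s01 / n0
  se <- sqrt(max(vcv[1, 1] + vcv[2, 2] - 2 * vcv[1, 2], 0))
  d <- pa$auc - pb$auc
  z <- if (se > 0) d / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(d == 0)
  structure(
    list(statistic = c(z = z), p.value = p,
         estimate = c("AUC a" = pa$auc, "AUC b" = pb$auc),
         method = "DeLong test for two correlated ROC curves",
         alternative = "two.sided",
         data.name = "paired scores"),
    class = "htest"
  )
}

#' Paired comparison of repeat-recording measurements
#'
#' Classical two-sided paired t-test between first and second measurements
#' of the same subjects (e.g. QTi or QT-RR slope from repeat Holter
#' recordings), with per-occasion means and SDs reported alongside.
#'
#' @param first,second Equal-length paired numeric vectors, n >= 2.
#' @return An object of classes `qti_paired` and `htest`, with `summary`
#'   holding mean and SD of each occasion and of the difference.
#' @export
paired_repeat_comparison <- function(first, second) {
  if (length(first) != length(second)) stop("paired vectors must have equal length")
  if (length(first) < 2L) stop("need at least 2 pairs")
  ht <- if (stats::sd(first - second) == 0) {
    # degenerate: identical pairs; t.test errors, but the answer is exact
    structure(list(statistic = c(t = 0), parameter = c(df = length(first) - 1),
                   p.value = 1, estimate = c("mean difference" = 0),
                   method = "Paired t-test", alternative = "two.sided",
                   data.name = "first vs second"),
              class = "htest")
  } else {
    stats::t.test(first, second, paired = TRUE)
  }
  ht$summary <- data.frame(
    occasion = c("first", "second", "difference"),
    mean = c(mean(first), mean(second), mean(first - second)),
    sd = c(stats::sd(first), stats::sd(second), stats::sd(first - second))
  )
  class(ht) <- c("qti_paired", "htest")
  ht
}

#' @export
print.qti_paired <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Paired repeat-recording comparison: %.1f +/- %.1f vs. %.1f +/- %.1f\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
  cat(sprintf("  mean difference %.2f, t = %.3f, p = %.3g\n",
              s$mean[3], unname(x$statistic), x$p.value))
  invisible(x)
}
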