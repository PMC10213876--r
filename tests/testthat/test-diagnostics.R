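# Cohort-level diagnostics: ROC/AUC, DeLong, cut-offs, 2x2 metrics,
# slope thresholds, paired repeat comparison.

test_that("midrank AUC equals the all-pairs probability estimator", {
  # perfectly separated scores
  r <- roc_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_true(any(r$roc$sensitivity == 1 & r$roc$specificity == 1))

  # hand cases from the counting oracle
  expect_equal(roc_auc(c(1, 2, 3), c(FALSE, FALSE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 2), c(FALSE, FALSE, TRUE))$auc, 0.75)

  # random cases, ties included, n <= 200: exact equality
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(2:100, 1); n0 <- sample(2:100, 1)
    s <- c(round(rnorm(n1, 0.8), 1), round(rnorm(n0), 1))
    l <- rep(c(TRUE, FALSE), c(n1, n0))
    brute <- mean(outer(s[l], s[!l], function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(s, l)$auc, brute)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC is monotone and the DeLong CI matches an independent implementation", {
  set.seed(7)
  s <- c(rnorm(60, 1.2), rnorm(80))
  l <- rep(c(TRUE, FALSE), c(60, 80))
  r <- roc_auc(s, l)
  expect_true(all(diff(r$roc$sensitivity) <= 1e-12))
  expect_true(all(diff(r$roc$specificity) >= -1e-12))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(l, s, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc_ci, ci[c(1, 3)])
})

test_that("DeLong self-comparison is exactly null and variance matches bootstrap", {
  set.seed(8)
  s <- rnorm(40) + rep(c(1, 0), each = 20)
  l <- rep(c(TRUE, FALSE), each = 20)
  self <- delong_compare(s, s, l)
  expect_equal(unname(self$statistic), 0)
  expect_equal(self$p.value, 1)

  # single-curve DeLong variance vs a 2,000-replicate bootstrap on n = 40
  r <- roc_auc(s, l)
  set.seed(9)
  boot <- replicate(2000, {
    ip <- sample(which(l), replace = TRUE)
    im <- sample(which(!l), replace = TRUE)
    sb <- c(s[ip], s[im])
    lb <- rep(c(TRUE, FALSE), each = 20)
    roc_auc(sb, lb)$auc
  })
  expect_lt(abs(stats::var(boot) - r$auc_var) / r$auc_var, 0.15)

  expect_error(delong_compare(s, s[-1], l), "equal length")
})

test_that("DeLong test holds its size under the null", {
  set.seed(10)
  rej <- mean(replicate(1000, {
    base <- rnorm(40) + rep(c(1, 0), each = 20)
    a <- base + rnorm(40, 0, 0.5)
    b <- base + rnorm(40, 0, 0.5)     # exchangeable noisy copies
    delong_compare(a, b, rep(c(TRUE, FALSE), each = 20))$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("the Youden cut-off equals an exhaustive threshold scan", {
  # perfectly separated: the smallest positive-class score (lower tie rule)
  r <- roc_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(optimal_cutoff(r), 10)

  set.seed(11)
  for (i in 1:20) {
    s <- round(c(rnorm(30, 1), rnorm(30)), 1)
    l <- rep(c(TRUE, FALSE), each = 30)
    r <- roc_auc(s, l)
    ct <- optimal_cutoff(r)
    # brute force over all candidate thresholds
    cand <- c(sort(unique(s)), Inf)
    j <- vapply(cand, function(t) mean(s[l] >= t) + mean(s[!l] < t) - 1,
                numeric(1))
    expect_equal(ct, cand[which.max(j)])
    # no threshold beats the selected one (asserted Youden optimality)
    cm <- classify_metrics(s, l, ct)
    expect_gte(cm$sensitivity + cm$specificity - 1, max(j) - 1e-12)
  }
})

test_that("classification metrics follow the 2x2 definitions", {
  perfect <- classify_metrics(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE), 5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  # hand-built 2x2: TP=7, FN=1, TN=9, FP=3
  scores <- c(rep(1, 7), rep(-1, 1), rep(-1, 9), rep(1, 3))
  labels <- rep(c(TRUE, FALSE), c(8, 12))
  m <- classify_metrics(scores, labels, 0)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(7, 1, 9, 3))
  expect_equal(m$sensitivity, 0.875)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$lr_pos, 3.5)
  expect_equal(m$accuracy, 16 / 20)

  expect_warning(classify_metrics(scores, labels, 99), "outside")
})

test_that("slope thresholds delegate to the 2x2 metrics and match control tails", {
  # simulated control slopes: fraction below 0.30 ~ 99%
  coh <- simulate_qti_cohort(qti_group_presets("by_genotype"),
                             n_per_cell = 20000, seed = 12)
  st <- slope_threshold_metrics(coh$alpha, coh$label)
  expect_equal(st[["0.30"]]$specificity,
               stats::pnorm(0.30, 0.168, 0.045), tolerance = 0.01)
  expect_equal(st[["0.25"]]$specificity,
               stats::pnorm(0.25, 0.168, 0.045), tolerance = 0.01)
  # delegation: identical to classify_metrics run manually on the slopes
  manual <- classify_metrics(coh$alpha, coh$label, 0.25)
  expect_identical(st[["0.25"]][names(st[["0.25"]])],
                   manual[names(manual)])

  # all slopes zero: specificity 1, sensitivity 0 at any positive cutoff
  z <- suppressWarnings(classify_metrics(rep(0, 20),
                                         rep(c(TRUE, FALSE), 10), 0.25))
  expect_equal(z$specificity, 1)
  expect_equal(z$sensitivity, 0)
})

test_that("sex-specific cut-offs report per-sex and pooled metrics", {
  coh <- simulate_qti_cohort(seed = 13)
  res <- classify_by_sex(coh)
  expect_named(res, c("male", "female", "pooled"))
  expect_equal(res$male$cutoff, 430)
  expect_equal(res$female$cutoff, 445)
  # pooled counts are the sums of the per-sex 2x2 tables
  expect_equal(res$pooled$tp, res$male$tp + res$female$tp)
  expect_equal(res$pooled$tn, res$male$tn + res$female$tn)
  # calibrated Gaussian cohorts land in the vicinity of the published
  # operating point (the normal model itself implies sensitivity ~0.82
  # at these cut-offs, below the printed 88%)
  expect_gt(res$pooled$sensitivity, 0.72)
  expect_gt(res$pooled$specificity, 0.90)
})

test_that("paired repeat comparison matches the textbook t statistic", {
  x <- c(5, 6, 8); y <- c(7, 6, 9)
  res <- paired_repeat_comparison(x, y)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(unname(res$statistic), t_hand)
  expect_equal(res$p.value, stats::t.test(x, y, paired = TRUE)$p.value)
  expect_equal(res$summary$mean, c(mean(x), mean(y), mean(d)))

  same <- paired_repeat_comparison(x, x)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  expect_error(paired_repeat_comparison(x, y[-1]), "equal length")
  expect_error(paired_repeat_comparison(1, 2), "at least 2")
})
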