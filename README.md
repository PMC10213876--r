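# qtiholter

Individualized QT interval (QTi) analysis from 24-hour Holter ECG
recordings, for researchers evaluating QT-based diagnosis of congenital
long QT syndrome (LQTS) and related repolarization phenotypes.

## The problem and the statistic

Diagnosis of LQTS from a resting ECG relies on the heart-rate-corrected QT
interval (QTc), but generalized correction formulae (Bazett, Fridericia,
Framingham) assume a population-average QT–RR relation, and roughly a
quarter of genotype-positive patients have a normal QTc. The individualized
QT interval sidesteps correction altogether: each subject's own QT–RR
relation is estimated from a 24-h ambulatory recording and read off at a
fixed heart rate.

The pipeline is:

1. Reduce the recording to one averaged beat waveform (*template*) per
   30-s window — up to 2,880 templates per 24 h.
2. On each template, locate the T-wave end by the **tangent method**: the
   intersection of the maximum-slope tangent of the T wave's terminal limb
   with the isoelectric line (the voltage at QRS onset). Pair the QT with
   the mean RR of the same window.
3. Fit the per-subject linear regression

   QT = α · RR + β

   where α (the *QT–RR slope*) quantifies QT rate dependence, and define

   **QTi = α · 1000 + β** — the QT interval at an RR of 1,000 ms (60 bpm).

4. Evaluate cohorts: empirical ROC curves with midrank AUC and DeLong
   confidence intervals, Youden cut-offs (sex-specific: 430 ms in males,
   445 ms in females), likelihood ratios, QT–RR-slope threshold rules, and
   paired t comparison of repeat recordings.

Validity filters follow ambulatory QT practice: template QT values above
700 ms are discarded, and recordings with less than 4 h of useful
registration are invalid.

Because raw clinical Holter archives are access-controlled, the package
includes a first-class synthetic Holter generator with exact ground truth:
beats are built from compact-support deflections with an exactly linear
terminal T limb (so the tangent T-end is a closed-form target), RR series
follow a circadian sinusoid plus AR(1) jitter, and cohort presets encode
published group parameters (controls vs. LQTS and the LQT1/LQT2/LQT3
genotypes, by sex). ISHNE (`.ecg`) Holter files can be written and read.

## Worked example

```r
library(qtiholter)

# draw a synthetic LQT2 subject from the published genotype preset
prof <- sample_subject(qti_group_presets("by_genotype"), "LQT2", "any", seed = 8)
prof
#> <qti_subject> LQT2_any_001 (LQT2, any)
#>   QT = 0.269 * RR + 246.4  (QTi = 515.4 ms, noise sd 6.0 ms)
#>   RR mean 807 ms, circadian amp 80 ms, jitter sd 40 ms, ectopy 0.20%

# synthesize a 2-h recording and run the full measurement chain
rec <- generate_recording(prof, duration_s = 7200, seed = 8)
res <- subject_qti(rec, min_points = 100, min_useful_h = 1)
res$fit
#> Individualized QT-RR regression
#>   QT = 0.2651 * RR + 250.1   (QT-RR slope alpha, intercept beta in ms)
#>   QTi (RR = 1000 ms): 515.1 ms
#>   Pearson r = 0.951 on 240 points, RR range 752-911 ms
```

The fitted slope (0.265 vs. true 0.269) and QTi (515.1 vs. true 515.4 ms)
recover the subject's programmed QT–RR relation from the raw signal; the
240 points are the 2-h recording's 30-s templates. `coef()`, `predict()`
(QT at any RR), `plot()` (the QT–RR scatter with the fitted line),
`residuals()` and `simulate()` work on the fit object as for any R model.

Cohort-level evaluation on a distribution-level simulated cohort:

```r
coh <- simulate_qti_cohort(seed = 1)          # sex-stratified preset sizes
males <- coh[coh$sex == "male", ]
roc <- roc_auc(males$qti_1000, males$label)
roc
#> <qti_roc> AUC 0.960 (95% CI 0.931-0.989), 115 cases / 102 controls
optimal_cutoff(roc)
#> [1] 422.1919
classify_by_sex(coh)$pooled
#> <qti_diag> cutoff NA: Sens 77%, Spec 96%, Acc 85%, +LR 19.3, -LR 0.242 (n = 455)
```

Here one simulated male cohort gives AUC 0.96 with a Youden cut-off of
422 ms, close to the published male cut-off of 430 ms; the pooled metrics
apply the fixed 430/445 ms sex-specific rule to all 455 subjects
(sensitivity and specificity of a single cohort draw scatter around the
model-implied values).

## Scope notes

The QT–RR relation is fitted by linear regression only (subject-specific
curvature is out of scope), and no arrhythmia classification, ST-segment
analysis or 12-lead ECG support is attempted. See the methods vignette
(`vignettes/qti-methods.Rmd`) for the model, parameter defaults and
limitations.
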