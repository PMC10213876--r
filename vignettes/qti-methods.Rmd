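---
title: "Individualized QT interval from Holter recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized QT interval from Holter recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtiholter)
```

## The model

The package estimates, per subject, the linear QT–RR relation

$$\mathrm{QT} = \alpha \cdot \mathrm{RR} + \beta + \varepsilon,$$

from template-level measurements of a long-term ECG, and summarizes it by
the individualized QT interval **QTi** $= 1000\,\alpha + \beta$ — the QT
interval the subject is expected to have at an RR interval of 1,000 ms
(60 bpm). Unlike Bazett- or Fridericia-corrected QTc, which impose a
population-average rate dependence on a single 10-s ECG, QTi uses the
subject's *own* rate dependence estimated across the full circadian RR
range, so no correction formula is involved. The slope $\alpha$ (the QT–RR
slope) is a phenotype in its own right: it is elevated in the LQT2 and
LQT3 genotypes of long QT syndrome.

Assumptions worth stating explicitly:

* **Linearity.** The true QT–RR relation is treated as linear across the
  observed RR range. Subject-specific curvature exists in real data; a
  curvilinear model is deliberately out of scope, so QTi inherits whatever
  bias linear extrapolation incurs for subjects whose RR never reaches
  1,000 ms. Extrapolated evaluations are flagged but not excluded, because
  subjects who never reach 60 bpm still need a QTi.
* **Quasi-stationarity within 30 s.** Each (QT, RR) point pairs a
  template-averaged QT with the mean accepted normal-to-normal RR of the
  *same* 30-s window. QT hysteresis (the lag of QT behind RR changes) is
  not modelled; its effect appears as scatter, not bias, provided rate
  changes are symmetric over 24 h.
* **Unweighted ordinary least squares.** Every valid template counts
  equally; no robust or weighted variant is applied by default. The
  Pearson correlation of the same points is reported as the quality of the
  linear fit.

## Measurement chain

1. **R-peak detection**: the channel is high-pass filtered by subtracting
   a 0.6-s moving average; local maxima of the absolute signal above an
   adaptive threshold (40% of the 99.95th percentile) are kept subject to
   a 250-ms refractory rule.
2. **Channel selection**: the lead with the largest median absolute
   T-region amplitude (100–400 ms after R) over a 5-min probe. Holter QT
   modules do not document their lead choice; a T-amplitude criterion
   conditions the tangent method best.
3. **Template averaging**: non-overlapping 30-s windows; beats aligned on
   the detected R peak; beats correlating below 0.9 with the window mean
   over a ±150-ms QRS region are rejected (ectopy/artifact); windows with
   fewer than 15 accepted beats yield no template.
4. **QRS onset**: the last sample at which the backward difference stays
   below 5% of the maximum QRS slope for two consecutive samples, found by
   walking back from the QRS upstroke. Two consecutive quiet samples are
   required so stationary points inside the QRS (e.g. the Q apex) are not
   mistaken for baseline. The voltage at onset defines the isoelectric
   line.
5. **Tangent T-end**: the T apex is sought 120 ms to min(600 ms, 0.9·RR)
   after onset (amplitude below 0.05 mV ⇒ `no_t_wave`); on the terminal
   limb (downslope of an upright, upslope of an inverted T) the
   maximum-slope point is found on a 5-point least-squares derivative, and
   the tangent line is then *re-estimated* by least squares over ±3
   samples around that point. The refit matters: taking the raw maximum of
   a noisy derivative overestimates the slope, and because the relative
   error is larger for the shallower limbs of long-QT templates this
   shortens long QTs more than short ones — an attenuation of $\alpha$ of
   about 2% and a QTi bias near −3 ms at realistic noise in our
   simulations, both of which the refit removes. The limb itself may be
   followed to 780 ms so that QT values above the 700-ms ceiling are
   measured and then *filtered* (flagged `qt_gt_700`) rather than being
   silently unmeasurable. The intersection with the isoelectric line is
   solved in continuous time, so T-end is not quantized to the sample
   grid.
6. **Validity**: ok measurements must satisfy 100 < QT ≤ 700 ms; a
   recording needs at least 4 h of ok 30-s windows (480 points), otherwise
   it is invalid and no regression is fitted. Both bounds are
   configuration parameters ([pipeline_config()]), and scaled-down
   property tests lower them alongside shorter recordings.

## The synthetic generator

The generator exists so the whole chain can be validated against exact
ground truth without access-controlled clinical data. Design choices:

* **Beat morphology**: compact-support raised-cosine deflections for
  P/Q/R/S and an asymmetric T wave whose terminal limb is *exactly
  linear*, reaching baseline precisely at the programmed QT. The tangent
  of a straight limb is the limb itself, so the tangent-method T-end is a
  closed-form target by construction, and the signal is identically zero
  outside the deflections, making QRS onset exact as well. Real T waves
  are not piecewise linear; what the construction buys is an oracle for
  the geometry, not electrophysiological realism.
* **Rhythm**: a single 24-h sinusoid on the subject mean RR (default
  amplitude 80 ms, slowest rate at the configurable night phase) plus
  stationary AR(1) jitter (default SD 40 ms, $\phi = 0.9$). This is the
  simplest process that spreads QT–RR points across a wide RR span, which
  is what identifies the regression; it does not model respiratory sinus
  arrhythmia, rate turbulence or atrial fibrillation.
* **Ground truth QT**: $\mathrm{QT}_k = \alpha\,\mathrm{RR}_{k-1} + \beta
  + N(0, \sigma_{QT}^2)$ with $\sigma_{QT}$ = 6 ms by default — chosen
  once as the template-level scatter consistent with the correlation
  coefficients near 0.9 reported for control Holter QT–RR fits, given the
  RR spread the generator produces.
* **Cohort presets**: per (group, sex) cells give normal distributions of
  QTi, QT–RR slope and mean RR with the published sample sizes. $\beta$ is
  never sampled: it is derived as $\mathrm{QTi} - 1000\alpha$, because
  cohort tables parameterize QTi, not the intercept.
* **Artifact**: white noise (0.02 mV), two slow sinusoids of baseline
  wander (0.05 mV), and 0.2% wide ectopic complexes (no P wave, discordant
  repolarization) to exercise the beat-rejection path. These levels are
  free parameters of the generator, not estimates of any particular
  recorder.
* **Determinism**: every sampling function takes an explicit seed and
  leaves the caller's RNG state untouched; per-subject seeds are derived
  from one master seed.

What passing tests on this generator *do* show: the tangent geometry,
window accounting, filter logic, regression algebra and diagnostic
statistics are correct, and parameters programmed into signals are
recovered through the full chain. What they do *not* show: robustness to
real-world morphology variation (notched or biphasic T waves, low-grade
noise bursts, electrode artifacts), which no synthetic fixture of this
kind can certify.

## Diagnostics

AUC is the Mann–Whitney midrank estimator (ties get half credit), with
variance and confidence intervals from DeLong placement values; two
correlated AUCs on the same subjects are compared by the DeLong z test.
The "optimal" cut-off criterion is the Youden index (sensitivity +
specificity − 1) — published reports rarely name their criterion, so a
different original criterion could shift recovered cut-offs by a few ms —
with ties broken toward the lower threshold, and positivity is
score ≥ cut-off throughout ("above is abnormal"). Likelihood ratios follow
the standard 2×2 definitions. Repeat-recording stability uses the
classical paired t-test; identical pairs are reported as t = 0, p = 1
rather than an error. No multiplicity adjustment is applied. Sex-specific
classification (430 ms male / 445 ms female by default) reports per-sex
and pooled metrics.

## Numerical choices and degenerate inputs

* T-end and QRS-onset indices are 0/1-based R sample indices internally;
  T-end is fractional (continuous-time intersection).
* Constant-QT fits define Pearson r = 0 (no linear association); constant
  RR is a fit failure (`no_rr_spread`), as is falling below the point
  minimum (`too_few_points`) — statuses, not silent omissions.
* Flat or all-zero channels yield an empty peak list with a warning, and
  `onset_fail` / `no_t_wave` qualities propagate without aborting the
  recording.
* ISHNE output quantizes at 1 µV per count; reading back a written file
  reproduces samples to that quantization and a second round trip is
  bit-identical. A CRC mismatch on read warns but does not abort.

## Problem sizes used in the tests

The test suite exercises the full chain at sizes chosen to keep the whole
suite comfortably reproducible on a single core: one full 24-h recording
at 200 Hz for the 2,880-template account; fifty 2-h subjects (QT noise
5 ms) for parameter recovery, where the mean absolute error is ~0.004 for
$\alpha$ and well under 1 ms for QTi; twenty cohorts of eight subjects
with paired 30-min re-simulated recordings at 128 Hz for repeat-recording
stability; 1,000 replicate Gaussian cohorts for the AUC calibration; and
10⁶ draws for the slope-rule specificities. These sizes are the package's
own choices; all are parameters, not constants.

## Known limitations

* The beat-rejection, channel-selection and minimum-beat rules stand in
  for undocumented proprietary Holter software behaviour; absolute
  agreement with any specific commercial QT module is not claimed.
* Whether the 700-ms QT filter should apply per template or per recording
  is ambiguous in ambulatory QT practice; it is applied per template here,
  and a recording whose every template exceeds it becomes invalid through
  the useful-registration rule.
* The Gaussian cohort presets reproduce distribution-level results (AUCs,
  slope-rule specificities, the 19-ms control sex difference in QTi).
  Operating-point metrics of real cohorts (e.g. a printed 88% sensitivity)
  are not exactly implied by normal distributions fitted to group means
  and SDs — the normal model yields ~82% at the same cut-offs — so the
  package treats them as descriptive, not as calibration targets.
* DeLong confidence intervals use the normal approximation; no exact
  small-sample interval is provided.
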