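---
title: "Methods: chemometric prediction of buffalo milk coagulation traits from MIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric prediction of buffalo milk coagulation traits from MIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific problem

Cheese yield depends on how milk coagulates after rennet addition. The
reference assay (a Formagraph-type lactodynamograph) measures three traits:

* **RCT** (rennet coagulation time, min) — time from rennet addition to the
  onset of gelation;
* **k20** (curd-firming time, min) — time from gelation onset until curd
  firmness reaches 20 mm;
* **a30** (curd firmness, mm) — firmness 30 min after rennet addition.

The assay is slow and destructive, so dairy programs would prefer to predict
these traits from the mid-infrared (MIR) spectrum already collected during
routine milk recording. `coagmir` implements the full chemometric pipeline
used in studies of Mediterranean buffalo bulk milk — preprocessing,
modified partial least squares (mPLS) calibration, outlier elimination,
cross-validation, external validation, and applicability interpretation —
together with a synthetic data generator that emulates the study conditions,
since the original spectra are not publicly deposited. A milk that does not
clot within the 30-min test window is *noncoagulating*: its traits are
censored (recorded `NA`) and the sample is excluded before modelling.

## Data model

Spectra are absorbance, log(1/T), on a wavenumber axis covering roughly
5000–900 cm^-1 (1060 points by default). Three water-dominated regions are
uninformative and always removed before modelling:
1566–1712, 1817–2696 and 2975–3700 cm^-1 (`water_regions()`,
`mask_regions()`). Sample records carry composition (fat, protein, casein,
lactose, somatic cell count) and the three coagulation traits.

## Preprocessing

Two orthogonal choices, swept as a grid:

* **Scatter correction** — `none`, SNV (each spectrum centred and scaled to
  SD exactly 1.0), Detrend (degree-2 polynomial baseline removed per
  spectrum by least squares), SNV+D (SNV then detrend), or MSC (each
  spectrum regressed on the calibration-mean spectrum; the fitted intercept
  is subtracted and the slope divided out, exactly inverting an affine
  distortion). MSC's reference is estimated on the calibration set only and
  reused for validation spectra.
* **Math treatment** — the WinISI code `d,gap,s1,s2`: a running-mean
  smoothing of window `s1`, a centred gap-difference derivative
  (`out[i] = x[i + ceil(gap/2)] - x[i - floor(gap/2)]`) applied `d` times,
  then a second smoothing of window `s2`. `0,0,1,1` is the identity. Edge
  points where a window or gap does not fit are trimmed, and the wavenumber
  axis is trimmed consistently, so treated spectra remain aligned with their
  axis. The treatments swept are the study grid: `0,0,1,1`, `1,4,4,1`,
  `1,8,8,1`, `2,5,5,1`, `2,10,10,1`.

Both stages are linear operators (given a fixed MSC reference), which the
test suite exploits as a property check.

## Modified PLS

`fit_mpls()` implements PLS1 by NIPALS with the Shenk–Westerhaus
modification: after each extracted factor, the X-residual at every
wavelength is divided by that wavelength's residual standard deviation
(sample SD; SDs below 1e-12 are floored to 1 to avoid dividing by numerical
zero). The y-residuals are not rescaled. With `standardize = FALSE` the
algorithm reduces exactly to textbook PLS1, which provides an independent
oracle for testing. Composite regression coefficients on the original
(centred) wavelength scale are accumulated through the standardization by a
rank-one operator recursion, so `coef()` at any factor count reproduces the
factorwise prediction recursion to machine precision. The inner loops run in
compiled code (RcppArmadillo) because the full study sweeps 75
trait-by-treatment cells at n ≈ 1700.

## Model selection and errors

Calibration uses seeded 15-fold cross-validation (`cross_validate()`). For
each factor count k the cross-validated error is
`SECV_k = sqrt(sum((oof_k - y)^2) / n)` from out-of-fold predictions. The
retained number of latent factors (LF) is the smallest k whose SECV is
within 2% of the minimum SECV, capped at 16 — the usual guard against
over-fitting marginal factors. SEC is computed from the pooled out-of-fold
residuals as `sqrt(RSS / (n - LF - 1))`, matching the convention in which
the calibration-set error statistic is the cross-validation error; R²CrV is
the squared Pearson correlation of out-of-fold predictions with the
reference values.

## Outlier elimination

Applied to the calibration set only (`outlier_pipeline()`):

1. **Global H (spectral outliers).** GH = Mahalanobis D² of a sample in the
   LF-dimensional score space divided by LF, using the maximum-likelihood
   covariance, so mean(GH) = 1 exactly on any sample (a trace identity the
   tests verify). Samples with GH > 3.0 are removed in a single pass.
2. **T statistic (chemical outliers).** Up to 3 rounds; each round refits by
   cross-validation and removes samples with
   `T = |prediction - reference| / SEC > 3.0`, stopping early when a round
   removes nothing.

If either stage would remove more than half the data the pipeline aborts,
and every flagged sample is recorded in an audit log (`write_outlier_log()`).

## Validation and interpretation

`split_calibration_validation()` makes a 75/25 split, choosing among 200
seeded random candidates the one with the most similar trait means and SDs
across the two sets. On the validation set `fit_statistics()` reports bias
(mean of predicted minus reference), slope (least-squares regression of
reference on predicted), SEP (SD of bias-corrected residuals, n − 1
denominator), R²ExV (squared Pearson correlation), and
RPD = SD(reference) / SEP.

`interpret_model()` maps (R²ExV, RPD) onto the published applicability
scale: *not recommended* (R² < 0.66 **and** RPD < 0.75), *screening*
(R² 0.66–0.81, RPD 1.7–2.2), *caution* (0.83–0.90, 2.3–3.5), *most
applications* (0.92–0.96, 3.6–4.9), *any application* (> 0.98, > 5.0).
The published scale leaves gaps (e.g. RPD between 0.75 and 1.7); values in
a gap, or combinations where only one metric is sub-screening, are labelled
**below screening** — a category this package adds so that the study's
actual results (R²ExV ≈ 0.40–0.57, RPD ≈ 1.29–1.52) have a well-defined
place: predictive, but insufficient even for rough screening. When the two
metrics disagree, the lower category wins. `slope_adequacy()` grades
|slope − 1|: ≤ 0.05 adequate, ≤ 0.15 acceptable, otherwise
imprecise-at-extremes.

## Synthetic data generator

`generate_dataset()` emulates the study conditions:

* **Composition** from truncated normals at the published bulk-milk moments
  (fat 7.87 ± 1.19%, protein 4.64 ± 0.35%, casein 3.68 ± 0.36%, lactose
  4.64 ± 0.18%), with protein–casein correlation 0.8; SCC lognormal,
  truncated to the published range.
* **Spectra** by Beer–Lambert superposition of Gaussian bands at the
  assigned wavenumbers: lactose 1045/1076/1157/1250, protein amide ~1550,
  casein 975 (phosphoserine P–O) plus an amide share at 1550, fat
  1390/1454/1743/2862/2927 cm^-1 — each scaled by the sample's constituent
  concentration — plus jittered water bands (1640/2120/3350), extra noise in
  the water regions, a random quadratic baseline, multiplicative scatter
  N(1, 0.05), and white instrument noise (SD 0.002). The casein bands matter:
  without them casein-driven traits would be recoverable only through the
  protein correlation, and the noiseless pipeline could not reach R² ≈ 1
  (a property the tests enforce).
* **Traits** linear in centred composition (RCT and k20 decrease with
  casein, a30 increases with casein and protein) plus independent trait
  noise, truncated to the published ranges. The trait-noise SDs were set
  with `calibrate_noise_for_target()` — a bisection on noise SD — so that
  the default pipeline lands at the published performance regime (a30
  R²ExV ≈ 0.57); they were fixed before the acceptance checks and are not
  tuned per run.
* **Noncoagulation** is a separate Bernoulli(0.0338) regime whose latent
  RCT exceeds the 30-min window; such samples get censored traits. A single
  normal RCT cannot simultaneously match the published retained moments
  (17.71 ± 3.75) and a 3.38% rate of exceeding 30 min, so the generator
  uses this mixture instead.

`inject_outliers()` plants spectral artifacts (localized Gaussian bumps plus
offset) and chemical errors (reference shifted by `magnitude` trait SDs) for
sensitivity studies.

All randomness is seeded; per-stage seeds are derived from the study seed
with a labelled substream hash, so rerunning a single trait reproduces its
rows bit-for-bit.

## Running the study

```{r}
library(coagmir)
dataset <- generate_dataset(synthetic_config(n_samples = 1736), seed = 1)
report <- run_study(dataset$spectra, dataset$records,
                    study_config(seed = 2))
print(report)
report_tables(report, "study-output")
```

The sweep covers 5 scatter corrections x 5 math treatments for each of the
three traits; the winner per trait is the combination with the lowest SECV
(ties: fewer factors, then grid order) — chosen on cross-validation, never
on the validation set, so the external statistics stay honest. At n = 1736
the full study takes about 5 minutes on one CPU.

## Numerical choices and limitations

* The residual-SD floor (1e-12 → 1) makes mPLS continue gracefully when a
  wavelength's residual variance collapses; rank exhaustion truncates the
  factor count with a warning rather than fabricating factors.
* Detrending solves the degree-2 fit on a centred/scaled wavenumber basis
  via QR; raw wavenumbers up to 5000 squared would make normal equations
  badly conditioned.
* SEC here is a cross-validation statistic (pooled out-of-fold residuals),
  not the apparent training error.
* The generator is a stylized emulation: Gaussian bands, linear trait
  models and a single censoring mechanism. It reproduces the published
  moments and the difficulty regime of the real study, but it cannot stand
  in for real buffalo bulk-milk spectra; conclusions about *which* scatter
  or math treatment wins on synthetic data need not transfer.
* Published headline numbers depending on the 1736 undeposited spectra are
  targets of consistency checks (arithmetic identities, interpretation
  bands, difficulty regime), not of exact reproduction.
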