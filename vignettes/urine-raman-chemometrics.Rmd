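---
title: "Chemometric analysis of urine Raman spectra: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric analysis of urine Raman spectra: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroraman)
```

## The problem

Dispersive Raman spectroscopy of urine records, in a single acquisition, the
vibrational bands of the major urinary solutes — urea, creatinine, glucose,
phosphate and proteins — superimposed on a broad fluorescence background and
the water band. Two clinical questions drive the analysis implemented here:

1. **Quantification.** Can the concentration of each biomarker be calibrated
   from the spectrum against a wet-chemistry reference assay?
2. **Screening.** Can subjects with diabetes and arterial hypertension
   (`DMHBP`), who are at elevated risk of renal damage, be separated from
   healthy controls (`CT`) directly from urine spectra?

The package implements the full chain — pre-processing, exploratory PCA,
PLS calibration with leave-one-out cross-validation, PLS-DA and LDA
classification, and evaluation — plus a seeded synthetic cohort generator,
because no patient spectra are publicly deposited for this design. The
generator provides ground truth, so every stage can be validated end to end.

## Pre-processing

Spectra are cleaned **in a fixed order**: despiking, fluorescence baseline
removal, water-band normalization; quality filtering then removes spectra
whose signal-to-noise ratio (SNR) falls below 10.

**Despiking** (`despike()`). Cosmic-ray artifacts are one-to-two channel
transients far above the local level. A channel is flagged when its residual
from a 5-channel running median exceeds 8 robust standard deviations and is
replaced by linear interpolation across the nearest clean channels. The
robust scale is the successive-difference estimator
$\hat\sigma = 1.4826\,\mathrm{median}(|\Delta y|)/\sqrt2$, which is
consistent for white noise and nearly blind to both spikes and band
structure; the median-absolute-residual of the running median itself
underestimates the noise and would flag genuine band apexes far more often.
When more than 20% of channels are flagged the function refuses: that
pattern is structure, not cosmic rays. One caveat is documented under
*Limitations* below.

**Baseline removal** (`remove_baseline()`). A plain least-squares polynomial
would ride up on the Raman peaks, so the 5th-order fit is the iterative
clipping variant: after each fit, the working spectrum is clipped to the fit
wherever it lies above it, and the fit is repeated until it changes by less
than `1e-6` in relative norm (cap: 100 iterations, non-convergence recorded
as a metadata flag, not an error). An exactly polynomial input is removed to
numerical precision, and `corrected + baseline` always reconstructs the
input.

**Water-band normalization** (`normalize_water_band()`). Each
baseline-corrected spectrum is divided by the trapezoidal area of the
1610–1710 cm⁻¹ window (center 1660 cm⁻¹, half-width 50 cm⁻¹). Water is in
vast excess in urine, so this area is an internal intensity standard that
cancels collection geometry and laser-power variation; the operation is
idempotent and makes spectra scale invariant. We read "normalization by the
water band" as *area* normalization; normalizing by the band height instead
differs only by a near-constant factor for a band of stable shape.

**SNR filtering** (`estimate_snr()`, `qc_filter()`). The SNR definition is
not standardized in the field, so the package uses: maximum intensity in
950–1050 cm⁻¹ (the window of the dominant urea band near 1002 cm⁻¹, the
strongest band of urine) divided by the standard deviation of the linearly
detrended 1750–1800 cm⁻¹ region, which is free of analyte bands. Spectra
with SNR < 10 are excluded; the per-spectrum QC table (SNR, spikes removed,
pass flag) is retained for audit.

## Model suite

**PCA** (`fit_pca()`): column-mean-centered SVD. Loadings are unit-norm
component directions over wavenumbers (spectrum-shaped); scores are the
per-spectrum projections. Note that part of the applied literature swaps
these two names — what some papers plot as "Scores" are loading vectors in
the conventional sense used here. Per-component group differences are tested
with a pooled-variance two-tailed Student's t-test on the scores
(`compare_component_scores()`), preceded by a Kolmogorov–Smirnov normality
check at p < 0.1 per group; when normality is rejected the t-test is still
reported but annotated, with no automatic nonparametric fallback.

**PLS regression** (`pls_fit()`, NIPALS): mean centering, no variance
scaling (all channels share units). With a single response the NIPALS
weights need no inner iteration, and the model collapses to the affine form
$\hat y = (x - \bar x)^\top b + \bar y$, verified in the tests against both
the sequential NIPALS prediction and an independent SIMPLS implementation.
At full rank PLS coincides with least squares, which the tests check against
the normal equations.

**Cross-validation** (`loocv_pls()`): for each latent-variable (LV) count
1..`max_lv` (default 10), every held-out unit is predicted by a model
refitted from scratch — centering and deflation included — on the remaining
units; RMSEcv and Pearson's r are recorded per LV and the LV count
minimizing RMSEcv is selected, ties toward fewer LVs. The **cross-validation
unit** is configurable and matters: each sample contributes six replicate
spectra, and holding out single spectra leaves the other five replicates of
the same sample in training. The default `cv_unit = "sample"` holds all
replicates of a sample out together, which is the leakage-free choice;
`cv_unit = "spectrum"` is provided because per-spectrum bookkeeping (visible
in published confusion tables whose totals count spectra) is common, and the
acceptance script reports the PLS-DA accuracy under both so the optimism of
the leaking variant can be seen directly.

**PLS-DA** (`plsda_fit()`/`plsda_classify()`): PLS regression on the class
code (CT = 1, DMHBP = 2), thresholded at the midpoint 1.5; a score exactly
at 1.5 is assigned to DMHBP (fixed, documented tie rule). The default
classifier uses 7 LVs.

**LDA** (`lda_fit()`/`lda_classify()`): class means, pooled within-class
covariance with a ridge of $10^{-6}$ times its mean diagonal for numerical
stability, empirical priors. Tests verify the boundary against the closed
form and predictions against `MASS::lda`.

**Evaluation**: DMHBP is the positive class, so sensitivity is the disease
detection rate. Displayed percentages are rounded half-up to one decimal;
raw fractions are kept internally. Reference-range flagging uses a strict
`>` against the applicable upper bound, with the wider of the male/female
bounds for subjects of unknown sex. Concentration conversions use
mg/dL = mmol/L × M/10 with M = 60.06 (urea), 113.12 (creatinine), 180.16
(glucose); total protein has no defined molar mass and is never converted.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the package targets: two
groups of 20 samples, six replicate spectra each (240 spectra), on a
400–1800 cm⁻¹ grid at 2 cm⁻¹ spacing — a spacing that resolves the ~12 cm⁻¹
bands. Per sample, a biomarker panel is drawn; per replicate, a spectrum is
synthesized as

$$I(\nu) = g \left[\sum_a c_a\, k_a\, S_a(\nu) + W(\nu)\right] + B(\nu) + \varepsilon(\nu) + \text{spikes},$$

with $S_a$ the unit component spectrum of analyte $a$ (Lorentzian bands,
FWHM 12 cm⁻¹, at the published urine band positions; Gaussian 40 cm⁻¹
protein bands across 1250–1700 cm⁻¹), $k_a$ a per-analyte response
coefficient, $W$ a broad Gaussian water band at 1660 cm⁻¹, $B$ a smooth
5th-degree polynomial fluorescence baseline with per-spectrum scale jitter,
$g$ a per-replicate gain (±10%, removed later by normalization),
$\varepsilon$ iid Gaussian noise, and Poisson-count cosmic spikes of 20–100
times the noise SD. With noise, baseline, water band, gain jitter and spikes
disabled, the model is exactly linear in the concentrations (superposition
to 1e-12, tested).

Concentration distributions default to the published clinical means and SDs
of the two groups (truncated at zero): e.g. CT glucose 0.23 ± 0.04 mmol/L.
DMHBP glucose is the one deliberately non-Gaussian case: a 75/25 mixture of
a controlled component (0.3 ± 0.1 mmol/L) and a frank-glycosuria lognormal
with mean ≈ 68 mmol/L, the minimal model that reproduces simultaneously the
published group mean (≈ 17.3 mmol/L), its huge SD, and the ~25% of patients
above the 0.83 mmol/L reference value.

Free parameters not fixed by published values were set once: the response
coefficients (1.5, 12, 5, 8, 4 intensity units per concentration unit for
urea, creatinine, glucose, phosphate, protein) keep the urea 1002 cm⁻¹ band
dominant as in real urine spectra; the noise SD (2 intensity units) was
chosen so that the six leading principal components carry > 98% of the
spectral variance — the structure reported for real urine spectra — while
per-spectrum SNR stays of order 100, typical of usable clinical
acquisitions. All randomness flows from a single seed in a documented order
(panel draws, then per replicate: gain, baseline jitter, noise, spikes), so
cohorts are bit-reproducible.

**What the generator does not emulate:** real urine contains dozens of
additional metabolites whose concentrations co-vary with disease status;
fluorescence photobleaching kinetics; instrument response drift; and any
nonlinear detector effects. Consequences for interpretation are discussed
below.

## Problem sizes and numerics

The default test and acceptance runs use the full 240-spectrum cohort for
end-to-end checks and 6–16-sample cohorts for structural tests; Monte-Carlo
oracles use 10–200 seeded draws, and distributional checks of the generator
use 10,000 draws. Degenerate inputs are handled explicitly: zero-variance
responses and single-class label sets are errors, a numerically flat noise
window yields an `Inf` SNR sentinel, an exhausted NIPALS residual freezes
further components with a warning, and the order-0 baseline reduces to an
iterated clipped mean.

## Limitations

- **Classifier ceiling of the simulated cohort.** In the generator the
  *only* group information is the five biomarker distributions, and they
  overlap substantially (their group means differ by well under one SD for
  every analyte except the glycosuric glucose tail). A linear classifier —
  LDA on the exact concentrations or PLS-DA on spectra that encode them —
  therefore plateaus near 65% held-out accuracy under sample-grouped
  cross-validation, regardless of spectral quality. Higher published
  accuracies on real spectra draw on matrix-wide compositional differences
  that the five-analyte forward model deliberately does not contain, and, in
  part, on per-spectrum cross-validation bookkeeping: switching to
  `cv_unit = "spectrum"` (replicates of the held-out sample remain in
  training) raises the PLS-DA accuracy markedly, which the acceptance script
  quantifies side by side. Passing recovery tests on this cohort therefore
  demonstrates calibration correctness, not expected clinical screening
  performance.
- **Despiking vs. sharp band apexes.** With 12 cm⁻¹ Lorentzians sampled
  every 2 cm⁻¹, the apex of the strongest bands deviates from the 5-channel
  running median by ~10% of the band height; at the default noise level that
  exceeds the 8-sigma threshold, so the single apex channel of the largest
  peaks is flattened by interpolation. The effect is systematic and small,
  and calibration quality is unaffected (cross-validated r ≈ 0.999 on the
  default cohort), but users despiking very high-SNR spectra with narrow
  bands may prefer a larger `despike_z`.
- **KS normality with estimated parameters.** The per-group normality check
  plugs the sample mean and SD into the Kolmogorov–Smirnov test, which makes
  it conservative (the Lilliefors correction is not applied); it is used
  only to annotate the t-test, never to gate it.
- **Two classes only.** The discriminant layer is deliberately binary;
  multi-group designs (e.g. staged renal disease) are out of scope.
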