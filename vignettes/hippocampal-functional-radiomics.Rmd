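---
title: "Hippocampal functional radiomics: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hippocampal functional radiomics: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipporad)
```

This vignette is the package's account of its science: what is computed,
under which conventions, which choices were genuinely open and how they were
fixed, and what the tests do and do not establish.

## The problem

Cognitive impairment affects a large fraction of Parkinson's disease
patients and is defined operationally by a MoCA score below 26. The
hypothesis behind this pipeline is that the *texture* of resting-state fMRI
derivative maps of the bilateral hippocampus — not just their mean level —
separates cognitively impaired (CI) from cognitively preserved (CP)
patients. The pipeline therefore turns each subject's 4D BOLD volume into
four scalar maps, summarises the hippocampus ROI of each map by 819
radiomics features, selects a sparse predictive subset, and builds two
classifiers: a linear rad-score with a Youden operating point, and a
logistic model on the selected features.

## Derivative maps and preprocessing order

The processing order is fixed as: drop equilibration volumes (done by the
generator, which emits the retained series) → linear detrend → 6 mm FWHM
Gaussian smoothing *only* for the ALFF/VMHC branch → 0.01–0.1 Hz ideal
(frequency-domain) band-pass → metric computation → z-transformation →
6 mm smoothing of the ReHo and DC maps. ReHo and DC are computed on
unsmoothed data because pre-smoothing would inflate local rank concordance
and inter-voxel correlations — the quantities these metrics measure; their
maps are smoothed only after z-scoring. Whether VMHC should use smoothed
input is genuinely open; we smooth it, reading the smoothing exception as
naming exactly ReHo and DC. The DC brain mask is exposed as a parameter
(`brain_mask` of the input volume) rather than hard-coded, since a
grey-matter restriction cannot be defined for synthetic data.

Conventions that a reimplementation must fix and we document:

* **Band-pass**: ideal filter; Fourier bins strictly outside the band (and
  DC) are zeroed. Out-of-band attenuation is numerically complete.
* **ALFF**: raw periodogram `|X_k|^2 / N` (no Welch windowing), mean of
  square roots over in-band bins. This keeps the definitional oracle exact
  and makes ALFF exactly homogeneous of degree 1 in the signal amplitude.
* **Kendall's W**: midranks for ties with the standard tie correction
  `m^2(n^3 - n) - m * sum(t^3 - t)` in the denominator; a voxel whose
  neighbourhood is entirely constant returns 0 with a warning. Ties are
  measure-zero for real BOLD but synthetic tests need determinism.
* **DC**: strictly positive threshold reading — only correlations
  `r > 0.25` are summed, self excluded; constant series contribute zero.
* **Z-transformation**: population (divide-by-N) standard deviation; the
  two-voxel map {1, 3} becomes {-1, +1}.
* **Smoothing**: separable Gaussian, `sigma = FWHM / (2 sqrt(2 log 2))`
  per axis in voxel units, reflective boundaries (avoids edge dimming of
  ROI-adjacent voxels), kernel normalised to sum 1.

A degenerate raw map (constant over the brain mask, which happens in
engineered test volumes) cannot be z-scored; the map object then carries a
zero z map with a warning rather than failing the whole run.

## The 819-feature roster

Per derivative map: 18 first-order + 73 texture features on the original
image, and the same 91 on each of 8 one-level undecimated 3D wavelet
sub-bands — 91 + 8 × 91 = 819; four maps give 3,276.

The texture composition is GLCM 22 + GLRLM 16 + GLSZM 16 + NGTDM 5 +
GLDM 14 = 73. Only this composition reproduces the printed totals; the
published feature lists do not pin the GLCM membership exactly, so we fix
it as the classical roster minus its three degenerate duplicates
(Dissimilarity ≡ DifferenceAverage, SumVariance ≡ ClusterTendency, and
SumAverage ≡ 2·JointAverage), which lands on 22 while keeping every
feature named in published coefficient tables (Idmn, Idn, Correlation,
ClusterShade, Imc1, Imc2).

Extractor conventions, all configurable where noted:

* **Discretisation**: fixed bin count (default 32) over the in-ROI
  min–max range, recomputed per wavelet sub-band. Derivative maps are
  z-scored and unit-free, so a fixed bin *width* would be meaningless.
* **Wavelet**: coif1, one level, stationary (undecimated) with symmetric
  extension, so sub-bands keep the grid shape and the ROI mask applies
  unchanged. Sub-band letters follow the stored (x, y, z) axis order.
  Basis is a config option (`wavelet`).
* **Matrix aggregation**: GLCM and GLRLM matrices are summed over the 13
  unique distance-1 directions before feature computation (the main
  alternative — per-direction features averaged afterwards — changes
  nothing qualitative but must be fixed for reproducibility).
* **Percentiles**: linear interpolation between order statistics
  (`quantile` type 7). Kurtosis is non-excess (Gaussian → 3); Variance and
  Skewness use population moments.
* **Degenerate conventions**: GLCM Correlation on a single-level ROI is 1
  (maximal homogeneity); NGTDM Coarseness of a uniform ROI returns the
  sentinel 1e6; a pairless (single-voxel) ROI yields zero GLCM features
  with a warning.

## Selection and models

The normalisation applied is min–max stretching of each feature to [0, 1]
using *training-cohort* extrema; validation values are transformed with the
same parameters and clipped. (The method description in the source
literature conflates z-scoring with [0, 1] stretching; the latter is what
its own words describe, so it is the default, with `method = "zscore"`
available.)

Redundancy pruning is greedy: while any pair of retained features has
|Spearman ρ| above 0.9, remove — from the currently worst pair — the member
with the larger mean |ρ| to all retained features, breaking exact ties by
dropping the lexicographically later name. This victim rule is not
specified anywhere; ours makes the result deterministic and column-order
independent, which a test verifies against a naive re-implementation.

The LASSO stage treats the binary label as a continuous response
(`(1/2n)·RSS + λ‖β‖₁`, the classical LassoCV formulation) with a 100-point
log grid from `λ_max = max_j |X_jᵀ(y − ȳ)|/n` down to `1e-3 λ_max`, λ
chosen by minimum mean CV squared error over label-stratified folds, and a
final refit on the full training cohort. Two properties are tested
analytically: all coefficients vanish at `λ ≥ λ_max` (with intercept ȳ),
and the coefficients converge to OLS as λ → 0. Note that the minimum-CV
rule characteristically admits a few decoy features with near-zero
coefficients; on a planted 2-signal/8-decoy design the signal pair always
enters and decoys stay an order of magnitude smaller, but a hard "at most
two decoys" guarantee would require the 1-SE rule, which this pipeline
deliberately does not use.

All selection — normalisation statistics, pruning, LASSO, the Youden
threshold, SMOTE, and the logistic fit — sees the training cohort only. A
leakage-audit test corrupts the validation data and asserts bit-identical
training artefacts. The split is stratified with total training size
`round(0.7 n)` allocated per class by largest remainder (89 subjects split
62/27; 10 split 7/3).

The positive class is CI throughout, and `score > threshold` declares CI.
Youden's J = sensitivity + specificity − 1 is maximised over ROC
thresholds, ties preferring higher sensitivity, then the lower threshold.
SMOTE balances the training set after the split (each synthetic minority
point interpolates towards one of its k = 5 nearest minority neighbours).
The logistic model adds a tiny L2 ridge (1e-4) so that separable synthetic
data — common under strong planted effects — still has a finite optimum;
the fit aborts if the penalised gradient does not vanish. AUC confidence
intervals use the DeLong placement-value variance; ACC/SEN/SPE use Wilson
intervals; AUC differences use the paired DeLong test (degenerate variance
returns p = 1 with a warning). Training metrics are reported on the
original (pre-SMOTE) training rows. SHAP values for the linear log-odds
model are exact under feature independence:
`φ_ij = w_j (x_ij − mean_bg(j))`, which a test verifies against full
coalition enumeration.

## Clinical associations

Within each diagnostic group, the partial correlation between each selected
feature and each clinical scale controls for age by residualising both
variables on (1, age); p-values use `t = r sqrt((n-2-k)/(1-r²))`. The
Bonferroni family size defaults to 7 — copying the convention of the
published analyses, which multiply by 7 even though 9 clinical measures are
listed; the constant is a parameter (`n_tests`) and we do not guess at the
discrepancy. Group comparisons pick chi-square for categorical variables
and gate t versus Mann–Whitney on per-group Shapiro–Wilk normality at
α = 0.05 (the gating rule is unstated in the source; this one is fixed and
documented).

## The synthetic cohort generator

The generator is the package's study design, not a tuning knob. Each
voxel's series is a sum of three parts, all reproducible from one global
seed that fans out to per-subject child seeds by a fixed counter scheme:

* a **locally shared** component: independent band-limited sources (sums of
  8 random-phase sinusoids with frequencies uniform in 0.01–0.1 Hz — energy
  exactly where ALFF integrates) are laid out mirror-symmetrically and
  averaged over each voxel's 27-neighbourhood, giving neighbouring voxels
  about two-thirds shared variance (what ReHo measures);
* a **homotopic** component, identical at a voxel and its x-mirror (what
  VMHC measures);
* white Gaussian noise (`noise_sd`, default 1 — component amplitudes are 1,
  so each shared part carries about a third of voxel variance, keeping CP
  ReHo/VMHC high but not degenerate).

Group effects multiply the two shared components by `1 − effect × severity`
inside the CI hippocampus (severity per CI subject uniform in 0.7–1),
lowering rank concordance and mirrored correlation by raising the relative
noise share — a multiplicative manipulation of exactly the correlation
structure the metrics quantify, rather than an additive lesion that would
mostly move ALFF. MoCA respects the diagnostic definition by construction
(CI < 26 ≤ CP, with the planted gap controlling distance); other scales are
drawn with a configurable correlation to the injected effect and clipped to
their instruments' ranges, with demographic distributions matched to
typical CI/CP cohort descriptions. The published study gives no effect-size
information usable for calibration, so the effect parameters are free
experimental knobs, not estimates.

What the generator does *not* emulate: haemodynamic response shape, head
motion, physiological noise spectra, registration/normalisation error,
anatomy, or non-stationarity. Spatial normalisation is out of scope —
signals are generated directly in a common grid. Passing recovery tests
therefore establish correctness of the computation, not clinical
performance.

## Problem sizes and numerical choices

The test suite runs on sizes chosen to make every check sharp but cheap:
definitional oracles on grids up to 8³ at 64 timepoints (tolerance 1e-8;
oracles are independently coded brute-force implementations, no shared
helpers); end-to-end recovery on a 12³ grid, 64 timepoints, 30 + 30
subjects with attenuation 0.8 (validation AUC must exceed 0.9); the null
arm re-runs the identical pipeline at 10 + 10 subjects over 20 seeds and
requires the validation AUC to be statistically indistinguishable from 0.5
(one-sample t-test). DeLong p-values are compared with a 20,000-replicate
marker-swap permutation oracle at n = 40 within 0.05 absolute — a bound
fixed in advance to cover both Monte-Carlo error and the normal
approximation at that n. The type-I error of the partial correlation is
checked over 1,000 null replicates at n = 60 against 0.05 ± 3 SE.

Determinism: every stochastic stage takes an explicit seed; the pipeline
manifest records content digests of the feature tables, split and summary,
and a repeated run with the same config reproduces them bit-for-bit.

## Known limitations

* The rad-score's Youden threshold can transfer poorly to the validation
  cohort when the training fit is heavily overdetermined (many selected
  features, small n): ordering (AUC) transfers, the operating point may
  not. This mirrors the behaviour of the method itself, not a bug.
* With very small validation cohorts the AUC is coarse-grained; null-arm
  statements are made across seeds, not per run.
* GLSZM/GLRLM matrices are summed over directions/whole ROI; per-direction
  variants are not implemented.
* The 73-texture membership beyond the printed counts is a documented
  convention (see above), as no authoritative roster exists.
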