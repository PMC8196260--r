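---
title: "Models and methods behind axispls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axispls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`axispls` analyzes how resting-state connectivity of anterior, middle and
posterior hippocampal segments relates to large-scale networks, episodic
memory and dopamine D2 receptor availability (D2DR). This vignette states
the models the package implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## Seed connectivity

For a seed ROI the connectivity map is the per-voxel Pearson correlation
with the unweighted ROI-mean time course, Fisher z-transformed
(z = atanh r). Two numerical rules cover inputs the transform itself does
not: |r| is clipped at 1 − 1e−7 before atanh (noiseless synthetic data
reach r = ±1 exactly, where atanh diverges), and zero-variance voxels or
seeds produce z = 0 plus a QC count instead of NaN — degenerate voxels
should be visible in a report, not propagate as missing values. The maps
assume fully preprocessed input; no filtering or smoothing is applied
here. ROI temporal SNR is the temporal mean of the ROI-average signal
divided by its temporal SD; a constant course has no defined SNR and is
flagged rather than silently dropped.

## Partial least squares

**Mean-centered (task) PLS.** With conditions c = aHC, mHC, pHC, the
condition-mean matrix M (one row per condition) is centered by its grand
column mean and decomposed, svd(M − 1·m̄ᵀ) = U S Vᵀ. Columns of V are
voxel saliences, columns of U condition saliences, and S² / ΣS² the
variance accounted per latent variable (LV). Brain scores are the plain
projections X·V (the voxel-by-salience sum). Because only condition means
are centered, raw scores carry a large common offset reflecting overall
connectivity level; the package therefore also reports
`brain_scores_centered` (scores relative to the grand condition-mean
score), the scale on which condition contributions straddle zero and on
which "a confidence interval covering zero" means "no reliable
contribution to the contrast". Numerically null singular values (below
1e−12 of the largest) are dropped; ties are broken by input order.

**Behavioral PLS.** Within each condition, X and the behavior block Y
(memory, D2DR) are z-scored across subjects and the condition-wise
correlation blocks R_c = Y_cᵀX_c/(n_c−1) are stacked and decomposed.
Correlation scores are per-condition correlations between behavior
columns and brain scores. A behavior column constant within a condition
is an error naming both; a constant X column contributes zeros (it has no
correlation with anything) and is counted.

**Permutation test.** Exchangeability units differ by variant: the
mean-centered null permutes condition labels within subject (is there any
condition structure at all?); the behavioral null permutes Y rows across
subjects within condition (is behavior linked to connectivity?). Each
LV's p is (1 + #{s_perm ≥ s_obs}) / (1 + n_perm) — never exactly zero,
with minimum 1/(1+n_perm). Defaults: 1000 permutations, minimum 100.

**Bootstrap.** Subjects are resampled with replacement, keeping each
subject's rows together across conditions; draws with fewer than 3
distinct subjects are redrawn and logged. Each bootstrap SVD is aligned
to the original solution by an orthogonal procrustes rotation of the
voxel saliences before aggregation — without alignment, the sign/axis
indeterminacy of the SVD corrupts the standard errors. The bootstrap
ratio BSR = salience/SE is a pseudo-z; |BSR| ≥ 3.3 (two-tailed normal
p < 0.001) marks reliable voxels.

Score and correlation CIs are percentile intervals, with one deliberate
choice: each bootstrap sample is projected onto the *original* saliences.
Re-estimating saliences per draw re-inflates the SVD-maximized contrast
in every draw and shifts the percentile interval away from the estimand;
in coverage experiments that convention collapsed coverage to near 10%,
while the fixed-projection convention restores nominal-width intervals.
A limitation remains either way: the sample contrast itself carries an
overfitting bias of order V·σ²/(n·s) (V voxels, n subjects, s the signal
singular value), so percentile CIs are only calibrated when the planted
or true contrast dominates that term. The coverage test in this package
states such a world (effect 6, n = 40, 50 voxels) deliberately; with weak
effects at small n the intervals undercover, which is a property of
percentile bootstrap around a biased estimator, not of the
implementation.

**Clusters.** Suprathreshold voxels are grouped by 26-connectivity
separately per salience sign, clusters with peaks closer than 10 mm are
merged (the weaker peak becomes a sub-peak), merged clusters under 10
voxels are dropped, and remaining local maxima are reported as sub-peaks.
Negative-salience clusters keep their sign, since the two network poles
correspond to opposite salience signs.

## Parcellation by group spatial ICA

Subject series restricted to the structure mask are variance-normalized
with **one scale per subject** (per-voxel z-scoring would erase the
voxel-level loading heterogeneity that makes spatial sources
identifiable), concatenated in time, reduced by PCA to k components, and
rotated to spatial independence by symmetric fixed-point ICA with the
tanh negentropy contrast (implemented in-package; no installed package
provides it). Components are unit-norm with the peak weight positive
(ICA sign is arbitrary) and carry an axis center: the y coordinate of
the peak-|weight| voxel — matching how component centers are reported at
discrete y values, rather than a center of mass. Components are paired
across hemispheres (centers within one voxel slice by default), matched
to expected axis centers by nearest distance — the published selection
criterion ("contribution to ROIs covering the greatest extension of the
axis") is not operationalizable and this nearest-center rule stands in,
recorded in provenance. ROI assembly thresholds each map at
|w| ≥ 2 SD(map) by default, resolves overlaps by larger |weight| (which
keeps the three ROIs disjoint), and merges hemispheres. At zero noise any
positive threshold separates gain-weighted signal from exactly-zero
background, so recovery tests use a permissive threshold; the SD-based
default targets noisy maps.

Default k = 5 per hemisphere exercises the selection logic at desk
scale; empirical component counts (19/18 in the motivating data) are
data-bound, not binding.

## Logan reference-tissue kinetics

The simplified reference Logan transform regresses
y(t) = ∫₀ᵗC_T/C_T(t) on x(t) = ∫₀ᵗC_R/C_T(t) over frames with mid-time
≥ t\*, slope = DVR, BPnd = DVR − 1. The k2′ correction term is omitted
(no value is stated in the motivating work); this is a documented
limitation that biases DVR slightly when C_R/C_T varies late in the
scan, and the maximum relative residual is reported as a curvature
diagnostic. Cumulative integrals are trapezoidal over frame mid-times
with zero activity at injection; the default schedule is 18 frames over
55 min; default t\* = 20 min leaves 7 frames (3 are required). Frames
with zero target activity are dropped with a warning. DVR is invariant
to rescaling both TACs. Bilateral BPnd is the arithmetic mean of the two
hemisphere fits — extrastriatal D2DR estimation is unreliable enough
that a whole-structure measure is preferred over per-segment ones.

## Cohort statistics

* **Memory composite**: per task, trial scores are summed (maxima
  32/16/24 for the default word / number–word / object–location
  battery); task sums are z-standardized across subjects, averaged, and
  rescaled to sample mean 50, SD 10 (T score). Zero-variance tasks are
  errors by name. Missing trials are mean-imputed beforehand
  (missingness is generated and assumed missing-completely-at-random).
* **ICV adjustment**: adjusted = raw − b·(ICV − mean ICV), b the
  least-squares slope — removes the ICV dependence exactly (|r| < 1e−10)
  while preserving the mean, avoiding the proportionality assumption of
  ratio adjustment.
* **Residualization**: OLS residuals on [intercept, nuisance] with the
  mean restored; rank deficiency is an error listing collinear columns.
* **Multivariate tests**: Wilks' Λ with Rao's F approximation, computed
  from sequential E/H cross-product matrices (covariates first, then the
  predictor block). Implemented by hand because `stats::manova` cannot
  handle a single dependent variable; with one dependent the statistic
  reduces exactly to the univariate ANCOVA F, and for several dependents
  it is cross-checked against `summary.manova(test = "Wilks")` in the
  tests. Degrees of freedom follow this sequential construction; other
  df conventions in the literature reflect unstated design-matrix
  choices and may differ.
* **Axis groups**: with positive = anterior network (the convention is
  fixed by requiring the aHC condition salience positive before
  classification), subjects with opposite-signed aHC/pHC scores express
  the division and are split by the mHC sign; all-same-signed subjects
  are all-anterior/all-posterior; same-signed aHC/pHC with opposing mHC
  is excluded. The motivating results leave reversed-division patterns
  (aHC−, pHC+) undefined; the rule above generalizes by keying division
  groups on the mHC sign alone, which partitions every sign pattern.
  Exact zero scores are an error unless a tolerance is configured, in
  which case sub-tolerance scores are excluded as unclassifiable — a
  measure-zero event on continuous data that should surface, not be
  silently assigned.
* **Group comparisons**: pooled-variance two-sample t with one-tailed p
  in the stated direction (the variance convention is unstated in the
  motivating work; pooled is the default, Welch available).

## The synthetic world

`gen_cohort()` states the world the tests run in: a 20×24×20 grid whose
y axis is the longitudinal axis; bilateral seed ROIs of 82/283/157
voxels (preserving the anterior < posterior size asymmetry that
motivates SNR controls); 170 volumes at TR 2 s; latent courses A/P/S as
smoothed (σ = 3 volumes) standardized Gaussian processes; anterior seed
voxels load on A, posterior on P, middle on a subject-specific
normalized mixture m·A + (1−m)·P with m ~ Beta(2,2), all seeds carry the
shared course S; three disjoint extra-hippocampal voxel sets carry A, P
and S scaled by per-subject adherence weights w ~ N(1, 0.25); memory and
D2DR are stated linear functions of standardized weights (couplings 0.5
and 0.3 to shared/posterior for memory, 0.4 to shared for D2DR) plus
Gaussian residuals; TACs follow the one-tissue reference model with
BPnd ~ N(0.3, 0.05) truncated at zero. Per-voxel signal gains
(uniform 0.5–1.5, drawn once per cohort) model partial-volume
heterogeneity — and are required for identifiability: with
piecewise-constant loadings every voxel of a block is an identical
sample and spatial ICA is rotation-degenerate.

Choices without stated values are calibration knobs fixed once: seed
amplitudes 1.1/0.95/0.7 and seed noise SDs 3/2/1.5 decrease anterior →
posterior, which together reproduce the observed aHC < mHC < pHC
ordering of ROI SNR; the signal baseline 1000 gives SNR its mean/SD
meaning; default n = 40 subjects keeps a full-grid cohort desk-scale.
Nuisance and volumetric columns echo published cohort-level summary
statistics (FD ≈ 0.19 ± 0.09 mm clipped to the observed range; segment
volumes 522/2178/1228 mm³ coupled to ICV; perfusion ≈ 40–43 mL/100
g/min) so downstream operations see realistic scales.

What the generator does **not** emulate: scanner physics, motion,
physiological noise and preprocessing (series stand in for fully
preprocessed data); spatial autocorrelation beyond block structure;
temporal autocorrelation beyond the latent-course smoothing; non-MCAR
missingness; arterial input functions (the reference course is a smooth
gamma-variate bolus). A green test therefore establishes correctness of
the estimators and their calibration under a second-order-accurate stand
in — not robustness to artifacts real preprocessing must remove.

Determinism: every generator and resampling function takes a seed and
restores the caller's RNG state; identical (config, seed) reproduces a
cohort bit for bit.

## Scaling in the test suite

Calibration experiments state their worlds explicitly: permutation
type-I error uses 500 pure-noise replicates (n = 20, 50 voxels,
n_perm = 200); CI coverage uses 200 replicates of a strong planted
contrast (see above); planted-contrast recovery runs at the full default
grid; the end-to-end behavioral invariant runs 50 replicates at study
scale n = 100 — at n = 40 the *sampled* behavior–weight couplings
occasionally collapse (a realized correlation near zero for a planted
0.4), which makes the first LV legitimately split the two behaviors; a
property of the sampled world, not of the pipeline. Grid and series
lengths in tests are desk-scaled versions of the defaults, chosen for
the test budget and stated in each test.
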