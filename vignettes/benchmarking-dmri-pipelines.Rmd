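---
title: "Benchmarking diffusion-MRI protocols and pipelines by tract-wise effect size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking diffusion-MRI protocols and pipelines by tract-wise effect size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractsens)
```

## The question the package answers

When a diffusion-MRI study compares a patient group against controls, the
size of the group difference it can detect depends not only on the biology
but on a stack of engineering choices: the acquisition protocol (field
strength, b-value scheme, resolution), the preprocessing pipeline (denoising,
Gibbs-ringing removal, motion/eddy-current correction), and how much the
images are smoothed before model fitting. `tractsens` quantifies the effect
of each of those choices on *sensitivity*, measured as Cohen's d of
white-matter tract parameters between two groups — and does so entirely on
synthetic cohorts with known ground truth, so the whole factorial experiment
is reproducible on a laptop without patient data.

The workflow mirrors a tract-based group study: simulate (or read) each
subject's diffusion-weighted series; preprocess it with one of the eight
pipelines (all subsets of {MPPCA, Gibbs, Eddy}, applied in that fixed
order); optionally smooth; fit the diffusion tensor (DTI) or kurtosis (DKI)
model by weighted linear least squares; summarize the scalar maps (FA, MD,
AD, RD, and MK, AK, RK for DKI) into probability-weighted per-tract means
and SDs; and compute per-tract effect sizes with their significance
thresholds.

## The statistical model

For each tract and parameter the groups are compared by

$$d = \frac{\bar u_{HC} - \bar u_{SLE}}{s}, \qquad
  s^2 = \frac{(n_{HC}-1)s^2_{HC} + (n_{SLE}-1)s^2_{SLE}}{n_{HC}+n_{SLE}-2},$$

the standardized mean difference with pooled SD. The sign of d for MD, RD
and AD is flipped (`sign_adjust()`) so that the expected pathological change
is positive for every parameter. Because the designs are unbalanced (more
patients than controls), the pooled SD mostly reflects the patient group.

Significance is judged against the null sampling distribution of d: with no
true effect, $d$ is exactly $t_{n_1+n_2-2}\sqrt{1/n_1 + 1/n_2}$ for normal
data, so the two-sided 5% threshold is the 97.5th percentile of the signed
null d (equivalently the 95th percentile of |d|). `null_threshold()`
computes it by Monte-Carlo simulation (the default, 2×10⁵ replicates) or by
the closed central-t form; the two agree within Monte-Carlo error. For the
study's cohort sizes (56/20, 63/20, 54/21) both give ≈ 0.51–0.52,
consistent with — and slightly below — the thresholds of 0.54 and 0.53 the
original analysis printed; the printed values are treated as upper
reference bounds, since their exact computation is not documented.
Multiplicity is handled two ways, reported side by side rather than
enforced: the Bonferroni level $1 - 0.05/72 \approx 99.9\%$
(`bonferroni_level()`), and the family-wise binomial argument
(`familywise_binomial()`): under a global null, more than seven of 72
tracts exceed the uncorrected threshold with probability 0.027 < 0.05, so
observing more than seven significant tracts indicates a real effect
somewhere.

Per-step impact (`step_impact()`) follows the matched-pairs construction:
every step appears in exactly four of the eight pipelines, so its impact is
the mean, over the four matched pairs, of the difference in tract-averaged
d between the pipeline with and without the step.

## The synthetic cohort generator

The generator (`build_atlas()`, `population_spec()`, `sample_subject()`,
`forward_signal()`, the artifact transforms) emulates the statistical
structure of a two-group tract study, not anatomy:

* **Geometry.** Tracts are smooth tubes (quadratic space curves with a
  Gaussian cross-section) inside an ellipsoidal brain; an even subset is
  laid down as mirrored left/right pairs. Probability maps have soft edges,
  like segmentation output.
* **Tissue.** Each tract has population baselines (FA spread over
  0.38–0.62 across tracts, MD 0.75×10⁻³ mm²/s, MK/AK/RK = 1.0/0.7/1.6 —
  typical adult white matter), and per-subject deviations drawn per
  *merged* tract (hemispheric homologues are correlated within a subject;
  the effect size is defined at the merged scale at which the analysis
  operates). Patients' means in the affected tracts are shifted by exactly
  `designed_d × between_subject_sd`, so the population effect size is known
  by construction. Background tissue is nearly isotropic with its own
  between-subject variability; overlapping tracts and background mix
  linearly (partial volume). Baseline S0 carries three features real
  magnitude images have and registration needs: white matter is ~15%
  darker than surrounding tissue, the brain edge falls off smoothly rather
  than as a step, and a smooth per-subject texture (12% SD) provides
  orientation information everywhere — a uniform sphere has none.
* **Signal.** The cumulant model
  $\ln S = \ln S_0 - b\,D_{app}(n) + \tfrac{b^2}{6} MD^2 W_{app}(n)$,
  evaluated per voxel per volume, with attenuation held at its minimum
  beyond $b^\* = 3D_{app}/(MD^2 W_{app})$ so the signal stays monotone in b
  (the model's validity range).
* **Artifacts.** Stationary Rician noise (σ = mean baseline / SNR), k-space
  truncation per in-plane axis (Gibbs ringing), episodic rigid motion
  (each volume moves with probability `motion_prob`; subjects do not move
  continuously, and absolute motion of an entire series is unobservable in
  principle), and eddy-current shear/scale along the phase-encode axis.
  Eddy distortions are the linear response of the gradient chain: one
  response coefficient per subject, applied to each volume scaled by its
  signed gradient amplitude along the phase encode
  ($\sqrt{b/b_{max}}\,n_y$) — so b=0 volumes are unaffected and opposite
  polarities distort oppositely. All applied transforms are recorded so
  recovery can be tested against ground truth.

What passing tests on these cohorts does *not* show: performance on real
anatomy (crossing fibres, CSF contamination, susceptibility distortion),
non-stationary noise, or segmentation variability — the atlas is shared
across subjects unless the caller supplies per-subject atlases.

## The processing steps

* **MPPCA** (`mppca_denoise()`): per sliding 5×5×5 patch, the
  volume-by-volume covariance of the patch matrix is eigendecomposed and
  the smallest c eigenvalues are classified as noise when their spread fits
  under the Marchenko–Pastur support width
  $e_{max} - e_{min} < 4\sqrt{c/M}\,\bar e$; σ² is the mean of the
  classified eigenvalues and the patch is rebuilt without them. The 5³
  patch keeps M = 125 ≥ N for every study scheme.
* **Gibbs removal** (`gibbs_unring()`): Fourier subvoxel shifts
  (k/(2M), default M = 20), per-voxel choice of the shift minimizing total
  variation in a ±3-voxel window, linear re-interpolation to the grid, with
  the two in-plane axes handled through complementary k-space weights.
* **Eddy/motion correction** (`correct_motion_eddy()`): registration-based,
  with three design choices that implementation experience forced:
  (1) *model-based references* — diffusion contrast differs per encoding
  direction (a tract dark along one gradient is bright along another), so
  volumes are never registered across contrasts; each volume is registered
  to its own leave-one-out model prediction (b=0 volumes to a
  leave-all-b0-out prediction where the shells allow it, else to the
  direction-averaged corrected DWI mean); (2) *shared eddy coefficients* —
  per-volume free affines confound rotation with shear, so the three eddy
  coefficients are estimated once per iteration across volumes through
  their known proportionality to the signed phase-encode gradient
  amplitude; (3) *parsimony gating with worst-first staging* — a moved
  volume distorts its direction-neighbours' predictions by a fraction of
  its own displacement, so estimated corrections below the minimum
  detectable motion (0.3 voxels), or much smaller than the current worst
  not-yet-corrected offender, are discarded; untouched volumes anchor the
  common frame and the spurious estimates vanish once the true offenders
  are fixed. The objective is normalized cross-correlation, maximized
  coarse-to-fine (Nelder–Mead with shrinking restarts and a parabolic
  finish); resampling is convolution-based tricubic (Catmull–Rom), applied
  once per volume; b-vectors are rotated by the polar rotation of the final
  transform. Known limitations, measured on synthetic data: recovery is
  accurate to well under a quarter voxel when a minority of volumes move
  (episodic motion), but degrades to roughly half a voxel when most volumes
  move independently — the prediction/registration feedback then has no
  clean anchor; and with fewer than roughly 20 volumes or grids under about
  24³ with little internal structure, spurious optima appear. These are
  properties of the information content, not parameters to tune around.
* **Smoothing** (`smooth_gaussian()`): separable Gaussian in voxel units
  with reflecting boundaries (sum-preserving); σ = 0 is the identity;
  applied after segmentation inputs are fixed and immediately before
  fitting — masks are never smoothed.

## Model fitting

`fit_wlls()` linearizes $\ln S$ and fits, per voxel, ordinary least squares
followed by two reweighted passes with weights equal to squared predicted
signals — the standard WLLS estimator. DKI is fitted in the substitution
$V = MD^2 W$, which keeps the problem linear; W is recovered by dividing by
the fitted MD². Voxels with non-positive signals or singular systems are
flagged and never contaminate neighbours. Eigenvalues are clamped at zero
for metric computation; kurtosis metrics are clipped to [−2, 10] with the
clip fraction reported. On noise-free signals the round trip
forward → fit recovers D, W and S0 to ~10⁻¹⁴ relative error.

## Tract statistics and QC

Voxels with tract probability below 0.5 are excluded outright; the
remaining voxels contribute probability-weighted means and SDs (population
form, Σp denominator — configurable to unweighted, since the original
description does not pin the convention down). Both the mean and the SD of
each parameter are carried forward as separate features. Left/right
homologues are averaged per subject before effect sizes are computed; a
72-tract layout reduces to 41 merged tracts. Tract-volume QC computes the
coefficient of variation of (p ≥ 0.5 voxel count × voxel volume) across
control subjects and flags tracts above 0.25 — far beyond anatomical volume
variation — as unreliable segmentations; both raw and QC-filtered counts
can be reported, since whether exclusions preceded the published
significant-tract counts is ambiguous.

## Numerical choices and degenerate inputs

b ≤ 50 s/mm² counts as b = 0 (scanner-reported small b-values). Directions
within 10⁻³ of unit norm are renormalized; worse is an error. Signals are
clamped at 10⁻⁶·max before logs. Zero pooled SD yields a missing d with a
log message rather than an error. The smoothing kernel is truncated at 4σ.
Registration bounds the search to physically plausible motion (|rot| ≤
0.2 rad, |trans| ≤ 5 voxels, |shear| ≤ 0.06, |scale−1| ≤ 0.08), which
excludes spurious optima at implausibly large rotations that mirrored tract
pairs would otherwise admit.

## Problem sizes used by the test suite

The acceptance checks run on one CPU in tens of minutes, with sizes chosen
as the smallest at which each property is informative: tensor round trips
on 100 random voxels of the full multi-shell scheme; the Marchenko–Pastur
oracle on a 32³×64 pure-noise volume; unringing on a 48² box phantom;
motion recovery on a 24³ grid with 12 tracts and 33 volumes, with four
diffusion-weighted volumes moved (≤ 3°, ≤ 2 voxels); designed-effect
recovery with the full 56 + 20 cohort, d = 0.8 on FA in 3 of 12 tracts,
20 replicates (the grand mean must land within ±0.15 of 0.8, and in every
replicate the affected tracts must average above the unaffected ones — a
per-tract strict ordering is not statistically attainable at these group
sizes, where a single tract's d has sampling SD ≈ 0.26); and the
qualitative pipeline properties on 2 + 2 cohorts of 20-volume scans
(eddy-correction impact positive under motion, zero without — the paired
pipeline contrast cancels the small-cohort sampling noise) and
14 + 14 cohorts of adjacent-tube partial-volume phantoms (FA sensitivity
declines monotonically with smoothing).

## Reproducing the study grid

```{r, eval = FALSE}
cfg <- study_config(
  protocols = c("3T-DTI", "3T-DKI", "7T-DTI"),
  smoothing_sigmas = seq(0, 1, by = 0.1),   # the full sweep
  seed = 1
)
res <- run_study(cfg)                        # 3 x 8 x 11 = 264 cells
plot_step_impact(step_impact(res$comparisons))
plot_smoothing_sweep(res$comparisons)
smoothing_sweep_report(res)
```

The full grid at the defaults takes hours; for exploration, restrict
`pipelines`, `smoothing_sigmas` or `group_sizes` as in the examples above —
cells are statistically independent, so subsets are meaningful.

## Known limitations

Tract segmentation itself is out of scope: the package ingests or
synthesizes probability atlases, it does not segment. Susceptibility
distortion and field maps are not modelled. The smoothing SD is interpreted
in voxel units (the original description gives none; resolution-relative
smoothing keeps the cross-protocol comparison fair). Harmonization and
outlier rejection are deliberately absent. Kurtosis ground truth is
axially symmetric per tract; crossing-fibre kurtosis is not represented.
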