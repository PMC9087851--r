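# tractsens

Tract-wise effect-size benchmarking for diffusion-MRI acquisition
protocols, preprocessing pipelines, and smoothing.

## The problem

Group studies with diffusion MRI — for instance comparing systemic lupus
erythematosus (SLE) patients against healthy controls (HC) — report group
differences in white-matter tract parameters: fractional anisotropy (FA),
mean/axial/radial diffusivity (MD/AD/RD), and for kurtosis imaging also
MK/AK/RK. How large those differences *appear* depends on engineering
choices made long before the statistics: the acquisition protocol (a 3T
single-shell DTI scheme, a 3T multi-shell DKI scheme, a 7T DTI scheme), the
preprocessing pipeline (any subset of Marchenko–Pastur PCA denoising,
Gibbs-ringing removal, and motion/eddy-current correction — eight pipelines
in all), and Gaussian pre-smoothing (SD 0 to 1 voxel).

`tractsens` makes that dependence measurable. It implements the full
benchmarking machinery — weighted-linear-least-squares DTI/DKI fitting,
probability-weighted tract statistics with volume-CoV quality control,
left/right merging, and the effect-size layer — together with a synthetic
two-group cohort generator whose ground truth (tissue parameters, designed
effect sizes, artifact transforms) is known exactly, so every step can be
validated and the whole factorial experiment runs without patient data.

The core statistic is Cohen's d with pooled SD,

    d = (mean_HC − mean_SLE) / s,
    s² = ((n_HC−1) s²_HC + (n_SLE−1) s²_SLE) / (n_HC + n_SLE − 2),

with signs flipped for MD/RD/AD so that expected pathological change is
positive everywhere. Under the null, d is a scaled central t, so the
two-sided 5% significance threshold for |d| is ≈ 0.52 for cohorts of
56 + 20 (Monte-Carlo and closed form agree); a Bonferroni correction for 72
tracts corresponds to the 99.9% per-test confidence level, and the exact
binomial tail P(more than 7 of 72 null tracts significant) = 0.027 < 0.05
gives a family-wise argument that needs no correction at all.

## A worked example

```r
library(tractsens)

cfg <- study_config(
  protocols        = "3T-DTI",
  pipelines        = list("none", "Eddy"),
  smoothing_sigmas = 0,
  group_sizes      = list("3T-DTI" = c(10L, 14L)),  # HC, SLE
  grid_shape       = 24, n_tracts = 12,
  designed_d       = 0.8,                 # FA effect in 3 merged tracts
  artifacts        = artifact_spec(snr_b0 = 40),
  seed             = 1
)
res <- run_study(cfg)
glance_tbl <- dplyr::filter(res$comparisons, parameter == "fa",
                            feature == "mean", tract == "tract01")
glance_tbl[, c("pipeline", "d", "significant_unc")]
#> # A tibble: 2 × 3
#>   pipeline     d significant_unc
#>   <chr>    <dbl> <lgl>
#> 1 none     0.702 FALSE
#> 2 Eddy     0.640 FALSE
res$thresholds$threshold_unc[1]
#> [1] 0.8575093
```

The affected tract's d lands in the neighbourhood of its designed 0.8 (a
single tract's d carries sampling error ≈ 0.4 at 10 + 14 subjects; the
full study sizes of 20 + 56 pin it down), and with no motion simulated the
Eddy pipeline leaves the comparison broadly unchanged — the small paired
difference reflects registration jitter on noisy data, which the
step-impact machinery averages over four matched pipeline pairs. The
significance threshold for so small a cohort is 0.86, which is why neither
cell is flagged. `plot_effect_sizes()`, `plot_step_impact()`,
`plot_smoothing_sweep()` and `plot_tract_qc()` visualize larger grids;
`tidy()` / `glance()` give broom-style access to any comparison.

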