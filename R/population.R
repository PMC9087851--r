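#' Two-group population specification
#'
#' Defines the statistical structure of a synthetic patient/control cohort:
#' group sizes, which tracts carry a group effect, on which tissue parameter,
#' the between-subject standard deviation of tract means, and the designed
#' population effect size. By construction the group mean shift equals
#' `designed_d * between_subject_sd` in the affected tracts, so the population
#' Cohen's d is exactly `designed_d`.
#'
#' Tract-mean baselines are fixed population constants: FA is spread evenly
#' over `fa_range` across tracts (white-matter-like anisotropy), MD is constant
#' at 0.75e-3 mm^2/s, and kurtosis baselines (MK, AK, RK) = (1.0, 0.7, 1.6)
#' are typical adult white-matter values.
#'
#' @param n_hc,n_sle Group sizes (controls, patients); each >= 2.
#' @param affected_tracts Character vector of tract names carrying the effect.
#' @param parameter Affected tissue parameter: `"fa"`, `"md"` or `"mk"`.
#' @param direction `-1` (patients lower, FA-like) or `+1` (patients higher,
#'   MD-like).
#' @param designed_d Target population Cohen's d in the affected tracts.
#' @param between_subject_sd Named numeric vector of between-subject SDs of
#'   tract means per parameter.
#' @param fa_range Range of per-tract baseline FA means.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_hc = 20, n_sle = 56,
                            affected_tracts = character(),
                            parameter = c("fa", "md", "mk"),
                            direction = -1,
                            designed_d = 0.8,
                            between_subject_sd = c(fa = 0.025, md = 0.04e-3, mk = 0.06),
                            fa_range = c(0.38, 0.62)) {
  parameter <- match.arg(parameter)
  if (n_hc < 2 || n_sle < 2) stopf("group sizes must be >= 2")
  if (!direction %in% c(-1, 1)) stopf("direction must be -1 or +1")
  sd_def <- c(fa = 0.025, md = 0.04e-3, mk = 0.06)
  sd_def[names(between_subject_sd)] <- between_subject_sd
  structure(
    list(n_hc = n_hc, n_sle = n_sle,
         affected_tracts = affected_tracts,
         parameter = parameter, direction = direction,
         designed_d = designed_d,
         between_subject_sd = sd_def,
         fa_range = fa_range,
         md_baseline = 0.75e-3,
         kurtosis_baseline = c(mk = 1.0, ak = 0.7, rk = 1.6),
         s0 = 1000),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec: %d HC vs %d SLE; d = %g on %s in %d tracts>\n",
              x$n_hc, x$n_sle, x$designed_d, toupper(x$parameter),
              length(x$affected_tracts)))
  invisible(x)
}

# Population-level per-tract baseline means (constant across subjects;
# left/right homologues share their baseline).
tract_baselines <- function(pop, atlas) {
  nt <- n_tracts(atlas)
  stem <- merged_tracts(atlas)$merged
  ms <- unique(stem)
  fa <- seq(pop$fa_range[1], pop$fa_range[2],
            length.out = length(ms))[match(stem, ms)]
  tibble::tibble(
    tract = atlas$tract_names,
    fa = fa,
    md = rep(pop$md_baseline, nt),
    mk = rep(pop$kurtosis_baseline[["mk"]], nt),
    ak = rep(pop$kurtosis_baseline[["ak"]], nt),
    rk = rep(pop$kurtosis_baseline[["rk"]], nt)
  )
}

#' Artifact specification for the simulator
#'
#' @param snr_b0 SNR of the baseline (b=0) signal; the Rician noise sigma is
#'   `mean in-mask S0 / snr_b0`. `Inf` disables noise.
#' @param motion_rot_deg,motion_trans_vox Per-volume rigid perturbation ranges
#'   (max absolute rotation in degrees, translation in voxels); 0 disables.
#' @param motion_prob Probability that a given volume is motion-affected
#'   (subject motion is episodic; unaffected volumes stay still).
#' @param eddy_shear,eddy_scale Per-volume maximal shear/scale along the
#'   phase-encode axis at the strongest gradient; scaled per volume by
#'   relative gradient amplitude (b=0 volumes get none).
#' @param gibbs_truncation Retained central k-space fraction per in-plane axis
#'   in (0, 1]; 1 disables truncation.
#' @param bias_field Amplitude of a smooth multiplicative bias field
#'   (0 disables).
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(snr_b0 = 30, motion_rot_deg = 0, motion_trans_vox = 0,
                          motion_prob = 0.3, eddy_shear = 0, eddy_scale = 0,
                          gibbs_truncation = 1, bias_field = 0) {
  if (snr_b0 <= 0) stopf("snr_b0 must be positive")
  if (motion_prob < 0 || motion_prob > 1) stopf("motion_prob must be in [0, 1]")
  if (gibbs_truncation <= 0 || gibbs_truncation > 1)
    stopf("gibbs_truncation must be in (0, 1]")
  structure(
    list(snr_b0 = snr_b0, motion_rot_deg = motion_rot_deg,
         motion_trans_vox = motion_trans_vox, motion_prob = motion_prob,
         eddy_shear = eddy_shear, eddy_scale = eddy_scale,
         gibbs_truncation = gibbs_truncation, bias_field = bias_field),
    class = "artifact_spec"
  )
}
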