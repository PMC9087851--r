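# Shared fixture builders. Everything is generated in code; heavier objects
# are cached per test run.

mini_scheme <- function(n_dirs = 12, n_b0 = 2, b = 1000, voxel = 2) {
  acquisition_scheme(
    c(rep(0, n_b0), rep(b, n_dirs)),
    rbind(matrix(0, n_b0, 3), tractsens:::hemisphere_dirs(n_dirs)),
    voxel_size = voxel, name = sprintf("mini-%d", n_dirs)
  )
}

# small cached atlas + one subject's tissue (noise-free paths reuse these)
.fix <- new.env()

fix_atlas <- function() {
  if (is.null(.fix$atlas)) .fix$atlas <- build_atlas(c(18, 18, 18), 6, seed = 7)
  .fix$atlas
}

fix_tissue <- function() {
  if (is.null(.fix$tissue)) {
    pop <- population_spec(n_hc = 2, n_sle = 2)
    .fix$tissue <- sample_subject(pop, fix_atlas(), "HC", seed = 5)
  }
  .fix$tissue
}

# box phantom dataset: sharp-edged block in a thin slab, n_vol volumes
box_dataset <- function(n = 48, nz = 3, n_vol = 2, value = 100) {
  arr <- array(0, c(n, n, nz, n_vol))
  lo <- round(n / 4) + 1
  hi <- round(3 * n / 4)
  arr[lo:hi, lo:hi, , ] <- value
  dwi_dataset(arr, acquisition_scheme(rep(0, n_vol), matrix(0, n_vol, 3), 2))
}

total_variation <- function(x) sum(abs(diff(x)))

# displacement (voxels) and rotation (degrees) of the composition of a true
# pull-back transform and its estimated correction, over interior points
residual_transform <- function(m_true, m_est, dims) {
  cm <- m_true %*% m_est
  ctr <- (dims + 1) / 2
  off <- dims / 3
  pts <- t(as.matrix(expand.grid(ctr[1] + c(-off[1], 0, off[1]),
                                 ctr[2] + c(-off[2], 0, off[2]),
                                 ctr[3] + c(-off[3], 0, off[3]))))
  disp <- cm[1:3, 1:3] %*% pts + cm[1:3, 4] - pts
  r <- tractsens:::polar_rotation(cm[1:3, 1:3])
  list(disp = max(sqrt(colSums(disp^2))),
       rot_deg = acos(min(1, max(-1, (sum(diag(r)) - 1) / 2))) * 180 / pi)
}
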