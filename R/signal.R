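#' Noise-free diffusion signal from a tissue model
#'
#' Evaluates the cumulant signal model
#' \deqn{\ln S(b, n) = \ln S_0 - b\,D_{app}(n) + \tfrac{b^2}{6}\,MD^2\,W_{app}(n)}
#' with \eqn{D_{app}(n) = n^T D n} and
#' \eqn{W_{app}(n) = \sum n_i n_j n_k n_l W_{ijkl}}. Because the quadratic
#' kurtosis term eventually curves the log-signal upward, attenuation is held
#' at its minimum beyond \eqn{b^* = 3 D_{app} / (MD^2 W_{app})}, which keeps
#' the signal monotone non-increasing in b (the model's validity range).
#'
#' @param tissue A `tissue_model` from [sample_subject()].
#' @param scheme An [acquisition_scheme()].
#' @param subject_id,group Metadata for the resulting dataset.
#' @return A [dwi_dataset()] of noise-free signals; `S(b=0)` equals `S0`.
#' @export
forward_signal <- function(tissue, scheme, subject_id = "subj", group = NA_character_) {
  dims <- dim(tissue$s0)
  nvox <- prod(dims)
  nvol <- length(scheme)
  s0v <- as.vector(tissue$s0)
  act <- which(s0v > 0)                    # signal is identically 0 elsewhere
  d6 <- matrix(tissue$d6, nvox, 6)[act, , drop = FALSE]
  w15 <- matrix(tissue$w15, nvox, 15)[act, , drop = FALSE]
  md <- rowMeans(d6[, 1:3, drop = FALSE])

  dapp <- apparent_diffusivity(d6, scheme$directions)   # nact x nvol
  wapp <- apparent_w(w15, scheme$directions)
  b <- matrix(scheme$bvalues, length(act), nvol, byrow = TRUE)
  b[, scheme_b0(scheme)] <- 0
  v <- md^2                                            # per voxel

  vw <- wapp * v
  # clip to the monotone range: cap b at the attenuation minimum b*
  bstar <- ifelse(vw > 0 & dapp > 0, 3 * dapp / vw, Inf)
  beff <- pmin(b, bstar)
  logatt <- -beff * dapp + beff^2 / 6 * vw
  logatt[b == 0] <- 0
  sig <- matrix(0, nvox, nvol)
  sig[act, ] <- s0v[act] * exp(logatt)
  dwi_dataset(array(sig, c(dims, nvol)), scheme,
              subject_id = subject_id, group = group)
}

#' Add stationary Rician noise
#'
#' Each voxel value S is replaced by \eqn{\sqrt{(S+\epsilon_1)^2 +
#' \epsilon_2^2}} with independent Gaussian \eqn{\epsilon \sim N(0,\sigma^2)}
#' and \eqn{\sigma =} mean in-mask baseline signal / `snr_b0` — the magnitude
#' noise model that produces the rectified noise floor at low SNR (a
#' zero-signal voxel acquires expectation \eqn{\sigma\sqrt{\pi/2}}).
#'
#' @param data A [dwi_dataset()].
#' @param spec An [artifact_spec()]; `snr_b0 = Inf` returns the input.
#' @param seed Integer seed.
#' @return A [dwi_dataset()] with noisy signals.
#' @export
add_rician_noise <- function(data, spec, seed = 1L) {
  if (!is.finite(spec$snr_b0)) return(data)
  b0 <- data$signal[, , , scheme_b0(data$scheme), drop = FALSE]
  s0mean <- mean(b0[b0 > 0])
  if (!is.finite(s0mean) || s0mean <= 0) s0mean <- mean(b0)
  sigma <- s0mean / spec$snr_b0
  withr::local_seed(seed)
  n <- length(data$signal)
  noisy <- sqrt((data$signal + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2)
  with_signal(data, array(noisy, dim(data$signal)))
}

#' Impose Gibbs ringing by k-space truncation
#'
#' Per axial slice and volume: 2D FFT, zero all frequencies outside the
#' central retained fraction along each in-plane axis, inverse FFT, magnitude.
#' Sharp edges acquire the characteristic truncation ripples.
#'
#' @param data A [dwi_dataset()].
#' @param spec An [artifact_spec()]; `gibbs_truncation = 1` is a no-op
#'   (up to FFT round-off, which is avoided by returning the input).
#' @return A [dwi_dataset()].
#' @export
apply_gibbs <- function(data, spec) {
  frac <- spec$gibbs_truncation
  if (frac <= 0) stopf("gibbs_truncation must be positive")
  if (frac >= 1) return(data)
  d <- dim(data$signal)
  keep1 <- kspace_keep(d[1], frac)
  keep2 <- kspace_keep(d[2], frac)
  kmask <- outer(keep1, keep2)
  out <- data$signal
  for (v in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      k <- stats::fft(data$signal[, , z, v]) * kmask
      out[, , z, v] <- Mod(stats::fft(k, inverse = TRUE)) / (d[1] * d[2])
    }
  }
  with_signal(data, out)
}

# logical mask of retained DFT frequencies for axis length n and fraction f
kspace_keep <- function(n, f) {
  k <- 0:(n - 1)
  ks <- ifelse(k > n / 2, k - n, k)
  abs(ks) <= f * n / 2
}

#' Impose per-volume motion and eddy-current distortions
#'
#' Each volume is resampled under a rigid transform (rotations, translations)
#' composed with an eddy-current transform (shear and scale along the
#' phase-encode axis, y). Motion is episodic: each volume is perturbed with
#' probability `motion_prob`. The eddy distortion is the linear response of
#' the gradient system: per-subject response coefficients are drawn once from
#' the configured ranges and each volume receives them scaled by its signed
#' relative gradient amplitude along the phase-encode axis
#' (\eqn{\sqrt{b/b_{max}}\, n_y}), so b=0 volumes receive motion only and
#' opposite gradient polarities distort in opposite directions. The applied
#' transforms are returned for recovery testing.
#'
#' @param data A [dwi_dataset()].
#' @param spec An [artifact_spec()] with motion/eddy ranges.
#' @param seed Integer seed.
#' @return List with `data` (corrupted [dwi_dataset()]) and `transforms`
#'   (tibble: one row per volume with the 9 transform parameters; see
#'   [me_params()]).
#' @export
apply_motion_eddy <- function(data, spec, seed = 1L) {
  d <- dim(data$signal)
  nvol <- d[4]
  withr::local_seed(seed)
  bmax <- max(data$scheme$bvalues)
  rot_max <- spec$motion_rot_deg * pi / 180
  # per-subject eddy response coefficients (linear in the gradient)
  eddy_resp <- c(stats::runif(2, -spec$eddy_shear, spec$eddy_shear),
                 stats::runif(1, -spec$eddy_scale, spec$eddy_scale))
  out <- data$signal
  rows <- vector("list", nvol)
  for (v in seq_len(nvol)) {
    moved <- stats::runif(1) < spec$motion_prob
    rot <- if (moved) stats::runif(3, -rot_max, rot_max) else c(0, 0, 0)
    tr <- if (moved) stats::runif(3, -spec$motion_trans_vox, spec$motion_trans_vox)
          else c(0, 0, 0)
    amp <- if (scheme_b0(data$scheme)[v] || bmax == 0) 0 else
      sqrt(data$scheme$bvalues[v] / bmax) * data$scheme$directions[v, 2]
    sh <- eddy_resp[1:2] * amp
    sc <- 1 + eddy_resp[3] * amp
    p <- me_params(rot, tr, shear = sh, scale_y = sc)
    if (any(p != me_params())) {
      m <- me_matrix(p, d[1:3])
      out[, , , v] <- resample_affine(data$signal[, , , v], m)
    }
    rows[[v]] <- tibble::tibble(volume = v, b = data$scheme$bvalues[v],
                                t(p) |> tibble::as_tibble())
  }
  list(data = with_signal(data, out),
       transforms = dplyr::bind_rows(rows))
}

#' Motion/eddy transform parameters and matrix
#'
#' `me_params()` packs rotation (radians, x/y/z), translation (voxels),
#' phase-encode shear (y from x, y from z) and y-scale into a named vector;
#' `me_matrix()` builds the corresponding pull-back affine in 1-based voxel
#' coordinates about the grid centre (output coords -> input coords).
#'
#' @param rot,trans Length-3 rotations (radians) and translations (voxels).
#' @param shear Length-2 shear of y with respect to x and z.
#' @param scale_y Scale factor along y.
#' @return `me_params()`: a list with `params` (named length-9 vector);
#'   `me_matrix()`: a 4x4 matrix.
#' @export
me_params <- function(rot = c(0, 0, 0), trans = c(0, 0, 0),
                      shear = c(0, 0), scale_y = 1) {
  rot <- unname(rot); trans <- unname(trans)
  shear <- unname(shear); scale_y <- unname(scale_y)
  c(rx = rot[1], ry = rot[2], rz = rot[3],
    tx = trans[1], ty = trans[2], tz = trans[3],
    syx = shear[1], syz = shear[2], sy = scale_y)
}

#' @rdname me_params
#' @param params Named length-9 parameter vector from `me_params()`.
#' @param dims Grid dimensions (length 3).
#' @export
me_matrix <- function(params, dims) {
  r <- rotation_matrix(params[c("rx", "ry", "rz")])
  s <- diag(3)
  s[2, 1] <- params[["syx"]]; s[2, 3] <- params[["syz"]]; s[2, 2] <- params[["sy"]]
  a <- r %*% s
  ctr <- (dims + 1) / 2
  m <- diag(4)
  m[1:3, 1:3] <- a
  m[1:3, 4] <- ctr - a %*% ctr + params[c("tx", "ty", "tz")]
  m
}

# Resample a 3D volume under a 4x4 pull-back affine (1-based voxel coords);
# order 3 = tricubic (Catmull-Rom, default), order 1 = trilinear (coarse
# search); outside-grid samples are 0.
resample_affine <- function(vol, m, order = 3L) {
  out <- resample_affine_cpp(vol, m[1:3, 1:3], m[1:3, 4], as.integer(order))
  array(out, dim(vol))
}

#' Rotate diffusion directions by a rigid rotation
#'
#' @param directions N x 3 direction matrix.
#' @param rot 3x3 rotation matrix.
#' @return N x 3 rotated directions.
#' @export
rotate_bvecs <- function(directions, rot) directions %*% t(rot)

#' Simulate one subject's acquired dataset
#'
#' Chains [sample_subject()], [forward_signal()] and the artifact transforms
#' in acquisition order: motion/eddy resampling, k-space truncation (Gibbs),
#' then Rician noise. A smooth multiplicative bias field (when enabled)
#' multiplies the signal before noise.
#'
#' @param pop A [population_spec()]. @param atlas A [tract_atlas()].
#' @param scheme An [acquisition_scheme()]. @param art An [artifact_spec()].
#' @param group Group label. @param seed Subject seed.
#' @param subject_id Subject label.
#' @return List: `data` (a [dwi_dataset()]), `tissue`, `transforms` (or NULL).
#' @export
simulate_subject <- function(pop, atlas, scheme, art, group, seed,
                             subject_id = sprintf("%s%03d", group, seed %% 1000L)) {
  tissue <- sample_subject(pop, atlas, group, seed = seed)
  data <- forward_signal(tissue, scheme, subject_id = subject_id, group = group)
  if (art$bias_field > 0) {
    data <- with_signal(data, data$signal * as.vector(bias_field(dim(data$signal)[1:3],
                                                                 art$bias_field)))
  }
  transforms <- NULL
  if (art$motion_rot_deg > 0 || art$motion_trans_vox > 0 ||
      art$eddy_shear > 0 || art$eddy_scale > 0) {
    me <- apply_motion_eddy(data, art, seed = derive_seed(seed, 11L))
    data <- me$data
    transforms <- me$transforms
  }
  if (art$gibbs_truncation < 1) data <- apply_gibbs(data, art)
  data <- add_rician_noise(data, art, seed = derive_seed(seed, 23L))
  list(data = data, tissue = tissue, transforms = transforms)
}

# Smooth multiplicative bias field: 1 + amplitude * separable cosine bump.
bias_field <- function(dims, amplitude) {
  g <- lapply(dims, function(n) cos(pi * (seq_len(n) - (n + 1) / 2) / n))
  1 + amplitude * outer(outer(g[[1]], g[[2]]), g[[3]])
}

#' Simulate a full two-group cohort
#'
#' @inheritParams simulate_subject
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return List: `subjects` (list of [simulate_subject()] results), `design`
#'   (tibble: subject_id, group, seed), `pop`, `atlas`.
#' @export
simulate_cohort <- function(pop, atlas, scheme, art, seed = 1L) {
  design <- tibble::tibble(
    subject_id = c(sprintf("HC%03d", seq_len(pop$n_hc)),
                   sprintf("SLE%03d", seq_len(pop$n_sle))),
    group = c(rep("HC", pop$n_hc), rep("SLE", pop$n_sle))
  )
  design$seed <- vapply(seq_len(nrow(design)),
                        function(i) derive_seed(seed, i), integer(1))
  subjects <- purrr::pmap(design, function(subject_id, group, seed) {
    simulate_subject(pop, atlas, scheme, art, group, seed, subject_id = subject_id)
  })
  list(subjects = subjects, design = design, pop = pop, atlas = atlas)
}
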