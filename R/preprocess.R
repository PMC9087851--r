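#' Enumerate the benchmark processing pipelines
#'
#' Returns the 8 pipeline configurations examined by the benchmark: applying
#' no processing at all ("none") plus all 7 non-empty subsets of
#' \{MPPCA, Gibbs, Eddy\}. Steps are always applied in the fixed order
#' MPPCA -> Gibbs -> Eddy. Every step appears in exactly 4 configurations,
#' giving 4 matched with/without pairs per step for impact analysis.
#'
#' @return A list of `pipeline_config` objects (fields `steps`,
#'   `smoothing_sigma`, `name`).
#' @export
enumerate_pipelines <- function() {
  steps_all <- c("MPPCA", "Gibbs", "Eddy")
  subsets <- list(character(0))
  for (s in steps_all) subsets <- c(subsets, lapply(subsets, function(x) c(x, s)))
  subsets <- subsets[order(lengths(subsets),
                           vapply(subsets, function(s) paste(s, collapse = ""), ""))]
  lapply(subsets, pipeline_config)
}

#' Pipeline configuration
#'
#' @param steps Character subset of `c("MPPCA", "Gibbs", "Eddy")`; order is
#'   normalized to the fixed application order MPPCA -> Gibbs -> Eddy.
#' @param smoothing_sigma Non-negative Gaussian smoothing SD in voxel units.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(steps = character(0), smoothing_sigma = 0) {
  fixed <- c("MPPCA", "Gibbs", "Eddy")
  bad <- setdiff(steps, fixed)
  if (length(bad)) stopf("unknown pipeline steps: %s", paste(bad, collapse = ", "))
  if (smoothing_sigma < 0) stopf("smoothing_sigma must be >= 0")
  steps <- fixed[fixed %in% steps]
  structure(
    list(steps = steps, smoothing_sigma = smoothing_sigma,
         name = if (length(steps)) paste(steps, collapse = "+") else "none"),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline '%s', sigma = %g>\n", x$name, x$smoothing_sigma))
  invisible(x)
}

#' Apply a processing pipeline to one dataset
#'
#' Steps run in the fixed order MPPCA -> Gibbs -> Eddy; smoothing (if any) is
#' applied last, immediately before model fitting. b-values are never altered;
#' only the Eddy step may rotate directions.
#'
#' @param data A [dwi_dataset()].
#' @param config A [pipeline_config()] (or character vector of steps).
#' @param ... Passed on to the step functions.
#' @return A [dwi_dataset()].
#' @export
apply_pipeline <- function(data, config, ...) {
  if (is.character(config)) config <- pipeline_config(config)
  for (s in config$steps) {
    data <- switch(s,
      MPPCA = mppca_denoise(data, ...)$data,
      Gibbs = gibbs_unring(data),
      Eddy  = correct_motion_eddy(data)$data
    )
  }
  if (config$smoothing_sigma > 0) data <- smooth_gaussian(data, config$smoothing_sigma)
  data
}

#' MPPCA denoising
#'
#' Random-matrix (Marchenko-Pastur) PCA denoising: within each sliding patch
#' the volume-by-volume covariance of the patch data matrix is
#' eigendecomposed, the smallest eigenvalues are classified as noise when
#' their spread fits under the Marchenko-Pastur support width
#' `e_max - e_min < 4 sqrt(c/M) * mean(e)` (c candidate noise eigenvalues, M
#' patch voxels), and the patch is reconstructed with the noise components
#' suppressed. Overlapping patch estimates are averaged; the per-voxel noise
#' level estimate (sigma) is returned.
#'
#' @param data A [dwi_dataset()] with at least 10 volumes.
#' @param patch_radius Patch radius in voxels (edge = 2r + 1; default 2 ->
#'   5x5x5 = 125 voxels, which keeps M >= N for all study schemes).
#' @param stride Patch-center stride (1 = fully sliding).
#' @return List: `data` (denoised [dwi_dataset()]) and `sigma` (3D array of
#'   noise SD estimates).
#' @export
mppca_denoise <- function(data, patch_radius = 2, stride = 1) {
  d <- dim(data$signal)
  if (d[4] < 10) stopf("MPPCA needs >= 10 volumes, got %d", d[4])
  if (2 * patch_radius + 1 < 2) stopf("patch smaller than 2x2x2")
  res <- mppca_cpp(data$signal, as.integer(d), as.integer(patch_radius),
                   as.integer(max(1L, stride)))
  list(data = with_signal(data, res$denoised), sigma = res$sigma)
}

#' Gibbs-ringing removal by optimal subvoxel shift
#'
#' Per axial slice, the image is split into two components by k-space filters
#' that assign each in-plane axis the frequencies it dominates; each component
#' is corrected along its axis by generating subvoxel-shifted copies via the
#' Fourier shift theorem (shifts k/(2 max_shift_steps), k = -M..M), choosing
#' per voxel the shift minimizing the total variation (sum of absolute first
#' differences) within +/- `window` voxels, and re-interpolating the chosen
#' shifted value back onto the grid.
#'
#' @param data A [dwi_dataset()].
#' @param max_shift_steps Number of shift steps M (>= 1); shifts span
#'   (-0.5, 0.5) voxels.
#' @param window Half-width of the total-variation window in voxels (>= 1).
#' @return A [dwi_dataset()].
#' @export
gibbs_unring <- function(data, max_shift_steps = 20, window = 3) {
  if (max_shift_steps < 1 || window < 1)
    stopf("max_shift_steps and window must be >= 1")
  d <- dim(data$signal)
  g <- gibbs_filters(d[1], d[2])
  out <- data$signal
  for (v in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      sl <- data$signal[, , z, v]
      f <- stats::fft(sl)
      ix <- Re(stats::fft(f * g$gx, inverse = TRUE)) / (d[1] * d[2])
      iy <- Re(stats::fft(f * g$gy, inverse = TRUE)) / (d[1] * d[2])
      out[, , z, v] <- unring_axis1(ix, max_shift_steps, window) +
        t(unring_axis1(t(iy), max_shift_steps, window))
    }
  }
  with_signal(data, out)
}

# Kellner-style complementary k-space weights: gx keeps the frequencies where
# variation is dominated by axis 1 (low k2), gy the complement; gx + gy = 1.
gibbs_filters <- function(n1, n2) {
  k1 <- 2 * pi * (0:(n1 - 1)) / n1
  k2 <- 2 * pi * (0:(n2 - 1)) / n2
  c1 <- 1 + cos(k1)
  c2 <- 1 + cos(k2)
  den <- outer(c1, rep(1, n2)) + outer(rep(1, n1), c2)
  gx <- outer(rep(1, n1), c2) / den
  gx[den == 0] <- 0.5
  list(gx = gx, gy = 1 - gx)
}

# Unring a 2D image along axis 1 (rows) by the subvoxel-shift search.
unring_axis1 <- function(img, m, window) {
  n1 <- nrow(img)
  fcol <- stats::mvfft(img)           # FFT along axis 1, per column
  k <- 0:(n1 - 1)
  ks <- ifelse(k > n1 / 2, k - n1, k)
  nyq <- (n1 %% 2 == 0) & (k == n1 / 2)

  best_tv <- array(Inf, dim(img))
  best_val <- img
  for (s in -m:m) {
    t <- s / (2 * m)
    ph <- exp(2i * pi * ks * t / n1)
    ph[nyq] <- cos(2 * pi * (n1 / 2) * t / n1)
    shifted <- Re(stats::mvfft(fcol * ph, inverse = TRUE)) / n1  # I(x + t)
    tv <- tv_axis1(shifted, window)
    # re-interpolate the shifted sample back to the grid position
    if (t > 0) {
      cand <- (1 - t) * shifted + t * rbind(shifted[1, , drop = FALSE],
                                            shifted[-n1, , drop = FALSE])
    } else if (t < 0) {
      a <- -t
      cand <- (1 - a) * shifted + a * rbind(shifted[-1, , drop = FALSE],
                                            shifted[n1, , drop = FALSE])
    } else {
      cand <- shifted
    }
    better <- tv < best_tv
    best_tv[better] <- tv[better]
    best_val[better] <- cand[better]
  }
  best_val
}

# Total variation along axis 1 within +/- window voxels of each pixel.
tv_axis1 <- function(img, window) {
  n1 <- nrow(img)
  dif <- abs(img[-1, , drop = FALSE] - img[-n1, , drop = FALSE]) # n1-1 rows
  padded <- rbind(matrix(0, window, ncol(img)), dif, matrix(0, window, ncol(img)))
  cs <- apply(padded, 2, cumsum)
  cs <- rbind(0, cs)
  # sum of dif rows (i - window) .. (i + window - 1), dif row j = |x[j+1]-x[j]|
  idx_hi <- pmin(seq_len(n1) + 2 * window, nrow(cs))
  idx_lo <- seq_len(n1)
  cs[idx_hi, , drop = FALSE] - cs[idx_lo, , drop = FALSE]
}

#' Motion and eddy-current correction by registration
#'
#' A simplified registration-based stand-in for full eddy-current correction.
#' Because diffusion contrast differs per encoding direction (a tract can be
#' dark in one volume and bright in another), diffusion-weighted volumes are
#' never registered across contrasts. The scheme is model-based:
#' \enumerate{
#'   \item b=0 volumes are rigidly registered to the earliest b=0 volume
#'     (which anchors the reference frame) and averaged into the baseline
#'     reference;
#'   \item the tensor model (DKI where the scheme supports it, else DTI) is
#'     fitted to the current corrected series and each diffusion-weighted
#'     volume is registered — rigid + phase-encode-axis shear/scale — to its
#'     own model-predicted image, which shares its contrast and lives in the
#'     baseline frame; the fit and registrations are iterated.
#' }
#' All objectives are Nelder-Mead maximization of normalized
#' cross-correlation, coarse-to-fine. Each volume is resampled exactly once
#' from the original data with its final transform; b-vectors are rotated by
#' the rigid rotation part. Volumes whose similarity to their reference
#' would worsen keep the identity transform (with a warning).
#'
#' @param data A [dwi_dataset()] with at least one b=0 volume.
#' @param max_iter Maximum Nelder-Mead iterations per stage.
#' @param model_iterations Model-fit / re-registration rounds.
#' @param estimate_eddy Estimate the shared eddy shear/scale coefficients
#'   (disable for purely rigid correction).
#' @param min_motion Minimum detectable motion (voxels): estimated
#'   corrections below it are discarded (see Details on gating).
#' @param verbose Print per-volume estimates per round.
#' @return List: `data` (corrected dataset with rotated scheme),
#'   `transforms` (tibble: per volume the estimated [me_params()] parameters,
#'   the exact 4x4 pull-back affine in the `matrix` list-column, and NCC to
#'   the volume's reference before/after correction).
#' @export
correct_motion_eddy <- function(data, max_iter = 400, model_iterations = 2,
                                estimate_eddy = TRUE, min_motion = 0.3,
                                verbose = FALSE) {
  d <- dim(data$signal)
  dims <- d[1:3]
  b0 <- scheme_b0(data$scheme)
  if (!any(b0)) stopf("need at least one b=0 volume")
  ib0 <- which(b0)
  idwi <- which(!b0)
  anchor <- data$signal[, , , ib0[1]]

  final_mat <- rep(list(diag(4)), d[4])
  working <- data$signal

  # stage 1: baseline reference anchored to the first b=0 volume
  corrected <- rep(FALSE, d[4])
  for (v in ib0[-1]) {
    par <- register_volume(data$signal[, , , v], anchor, use_eddy = FALSE,
                           max_iter = max_iter, screen_motion = 0.8 * min_motion)
    if (is.null(par) || displacement_magnitude(par, dims) < min_motion) next
    corrected[v] <- TRUE
    final_mat[[v]] <- me_matrix(par, dims)
    working[, , , v] <- resample_affine(data$signal[, , , v], final_mat[[v]])
  }

  # stage 2: iterate model fit and registration of every volume (b=0 ones
  # included) to its own model prediction, so the whole series converges to
  # one common frame — the least-squares model frame. Rigid motion is
  # estimated per volume; the eddy shear/scale coefficients are tied across
  # volumes through their physical proportionality to the signed gradient
  # amplitude along the phase-encode axis, which removes the rotation/shear
  # degeneracy a free per-volume affine would have.
  model <- if (scheme_dki_capable(data$scheme)) "DKI" else "DTI"
  pred <- NULL
  bmax <- max(data$scheme$bvalues)
  amp <- ifelse(b0, 0, sqrt(data$scheme$bvalues / bmax) *
                  data$scheme$directions[, 2])
  eddy_coef <- c(0, 0, 0)   # (shear y<-x, shear y<-z, scale y) per unit amplitude
  rigid_par <- vector("list", d[4])
  est_par <- vector("list", d[4])   # raw estimates: warm starts survive gating
  for (v in ib0) rigid_par[[v]] <- matrix_to_params(final_mat[[v]], dims)
  if (length(idwi)) {
    for (it in seq_len(model_iterations)) {
      pred <- loo_predict(working, data$scheme, model)
      for (v in seq_len(d[4])) {
        prev <- est_par[[v]] %||% rigid_par[[v]]
        par <- register_volume(data$signal[, , , v], pred[, , , v],
                               use_eddy = FALSE, max_iter = max_iter,
                               init = if (is.null(prev) ||
                                          displacement_magnitude(prev, dims) == 0)
                                 NULL else
                                 unname(prev[c("rx", "ry", "rz", "tx", "ty", "tz")]),
                               fixed_eddy = c(eddy_coef[1:2] * amp[v],
                                              1 + eddy_coef[3] * amp[v]),
                               screen_motion = 0.8 * min_motion)
        if (is.null(par)) par <- prev %||% me_params()
        est_par[[v]] <- par
        rigid_par[[v]] <- par
        if (verbose)
          message(sprintf("it %d vol %d: est disp %.3f", it, v,
                          displacement_magnitude(par, dims)))
      }
      if (estimate_eddy)
        eddy_coef <- estimate_eddy_coef(data$signal, pred, idwi, rigid_par, amp,
                                        dims, eddy_coef)
      # parsimony gate with worst-first staging: a genuinely moved volume
      # distorts its direction-neighbours' predictions by a fraction of its
      # own displacement, so neighbours transiently show spurious estimates.
      # A not-yet-corrected volume is therefore only corrected when its
      # estimate is above the minimum detectable motion AND comparable to
      # the worst not-yet-corrected offender; the rest stay untouched and
      # anchor the common frame. Once the real offenders are corrected the
      # spurious estimates vanish and later passes refine freely.
      disp_est <- vapply(seq_len(d[4]), function(v)
        displacement_magnitude(combine_rigid_eddy(rigid_par[[v]], eddy_coef,
                                                  amp[v]), dims), numeric(1))
      # cross-contrast b=0 registration (single-shell schemes reference the
      # DWI mean) carries a bias of a few tenths of a voxel: such estimates
      # need clearly larger evidence and never set the staging scale
      xc_b0 <- b0 & isTRUE(attr(pred, "b0_cross_contrast"))
      new_est <- disp_est[!corrected & !xc_b0]
      stage_gate <- max(min_motion, if (length(new_est)) 0.5 * max(new_est) else 0)
      vol_gate <- rep(stage_gate, d[4])
      vol_gate[xc_b0] <- pmax(vol_gate[xc_b0], 2 * min_motion)
      for (v in seq_len(d[4])) {
        if (!corrected[v]) {
          if (disp_est[v] >= vol_gate[v]) corrected[v] <- TRUE
          else rigid_par[[v]] <- me_params()
        }
        par <- combine_rigid_eddy(rigid_par[[v]], eddy_coef, amp[v])
        # the gate covers the combined transform: a sub-threshold residual
        # eddy component alone is not worth the interpolation cost
        final_mat[[v]] <- if (displacement_magnitude(par, dims) < min_motion)
          diag(4) else me_matrix(par, dims)
        working[, , , v] <- if (identical(final_mat[[v]], diag(4)))
          data$signal[, , , v]
        else resample_affine(data$signal[, , , v], final_mat[[v]])
      }
    }
  }

  # apply + bookkeeping: every volume was resampled once from the original
  out <- data$signal
  dirs <- data$scheme$directions
  rows <- vector("list", d[4])
  for (v in seq_len(d[4])) {
    m <- final_mat[[v]]
    vol <- data$signal[, , , v]
    refv <- if (is.null(pred)) anchor else pred[, , , v]
    sim_before <- ncc(vol, refv)
    corrected <- if (identical(m, diag(4))) vol else resample_affine(vol, m)
    sim_after <- ncc(corrected, refv)
    if (sim_after < sim_before) {
      warnf("registration of volume %d worsened similarity; keeping identity", v)
      m <- diag(4)
      corrected <- vol
      sim_after <- sim_before
    }
    out[, , , v] <- corrected
    rot <- polar_rotation(m[1:3, 1:3])
    dirs[v, ] <- rotate_bvecs(matrix(data$scheme$directions[v, ], 1), t(rot))
    rows[[v]] <- tibble::tibble(volume = v, b = data$scheme$bvalues[v],
                                t(matrix_to_params(m, dims)) |> tibble::as_tibble(),
                                matrix = list(m),
                                ncc_before = sim_before, ncc_after = sim_after)
  }
  scheme <- data$scheme
  scheme$directions <- dirs
  res <- with_signal(data, out)
  res$scheme <- scheme
  list(data = res, transforms = dplyr::bind_rows(rows))
}

# Leave-one-out model predictions: each volume's noise-free image is
# predicted from a log-domain least-squares fit of all OTHER volumes (rank-1
# downdate of the normal equations), so a volume's own displacement cannot
# leak into its reference. b=0 volumes are predicted from a fit excluding
# ALL b=0 rows (the baseline extrapolates from the diffusion-weighted
# shells), because the b=0 volumes can share a common displacement that
# plain leave-one-out would never see. Voxels with non-positive signals
# fall back to the supplied data.
loo_predict <- function(working, scheme, model) {
  d <- dim(working)
  dims <- d[1:3]
  nvox <- prod(dims)
  n <- d[4]
  b0 <- scheme_b0(scheme)
  a <- design_matrix(scheme, model)
  y <- t(matrix(working, nvox, n))          # n x nvox
  okv <- colSums(y <= 0) == 0
  eps <- 1e-6 * max(y)
  y[y < eps] <- eps
  l <- log(y)
  g <- crossprod(a)
  h <- crossprod(a, l)                      # p x nvox
  cap <- log(2 * max(working))
  pred <- working
  # shared leave-all-b0-out system (used for every b=0 volume). For a
  # single-shell scheme this system is singular (S0 and mean diffusivity
  # trade off exactly); there the direction-averaged mean of the current
  # diffusion-weighted volumes — dominated by the same S0 structure —
  # serves as the b=0 reference instead.
  gb <- g - crossprod(a[b0, , drop = FALSE])
  hb <- h - crossprod(a[b0, , drop = FALSE], l[b0, , drop = FALSE])
  coef_b0 <- if (rcond(gb) > 1e-8) tryCatch(solve(gb, hb), error = function(e) NULL)
             else NULL
  dwi_mean <- if (is.null(coef_b0) && any(!b0))
    array(rowMeans(matrix(working[, , , !b0], nvox)), dims)
  else NULL
  b0_cross_contrast <- is.null(coef_b0)
  for (v in seq_len(n)) {
    if (b0[v]) {
      if (is.null(coef_b0)) {
        if (!is.null(dwi_mean)) pred[, , , v] <- dwi_mean
        next
      }
      coef <- coef_b0
    } else {
      gv <- g - tcrossprod(a[v, ])
      hv <- h - a[v, ] %o% l[v, ]
      coef <- tryCatch(solve(gv, hv), error = function(e) NULL)
    }
    if (is.null(coef)) next
    logs <- drop(a[v, ] %*% coef)
    vals <- exp(pmin(logs, cap))
    bad <- !okv | !is.finite(vals)
    vals[bad] <- working[, , , v][bad]
    pred[, , , v] <- array(vals, dims)
  }
  attr(pred, "b0_cross_contrast") <- b0_cross_contrast
  pred
}

# Largest displacement (voxels) a transform produces over the central
# two-thirds of the grid.
displacement_magnitude <- function(par, dims) {
  m <- me_matrix(par, dims)
  ctr <- (dims + 1) / 2
  off <- dims / 3
  pts <- t(as.matrix(expand.grid(ctr[1] + c(-off[1], 0, off[1]),
                                 ctr[2] + c(-off[2], 0, off[2]),
                                 ctr[3] + c(-off[3], 0, off[3]))))
  disp <- m[1:3, 1:3] %*% pts + m[1:3, 4] - pts
  max(sqrt(colSums(disp^2)))
}

# Merge a rigid parameter vector with global eddy coefficients scaled by a
# volume's gradient amplitude along the phase-encode axis.
combine_rigid_eddy <- function(rigid, coef, amp) {
  me_params(rot = rigid[c("rx", "ry", "rz")],
            trans = rigid[c("tx", "ty", "tz")],
            shear = coef[1:2] * amp, scale_y = 1 + coef[3] * amp)
}

# Estimate the 3 global eddy coefficients by maximizing the summed NCC of the
# strongly phase-encode-weighted diffusion volumes (|amplitude| >= half the
# maximum — the ones that carry the eddy signal) against their model
# predictions, with the rigid parts held fixed. Nelder-Mead followed by a
# parabolic polish.
estimate_eddy_coef <- function(signal, pred, idwi, rigid_par, amp, dims, init) {
  strong <- idwi[abs(amp[idwi]) >= 0.5 * max(abs(amp[idwi]))]
  if (!length(strong)) strong <- idwi
  obj <- function(cf) {
    if (any(abs(cf) > 0.1)) return(1 + sum(pmax(abs(cf) - 0.1, 0)))
    s <- 0
    for (v in strong) {
      m <- me_matrix(combine_rigid_eddy(rigid_par[[v]], cf, amp[v]), dims)
      s <- s - ncc(resample_affine(signal[, , , v], m, order = 1L), pred[, , , v])
    }
    s / length(strong)
  }
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 100, reltol = 1e-10,
                                     parscale = rep(0.02, 3)))
  cf <- fit$par
  delta <- rep(0.004, 3)
  for (sweep in 1:2) {
    for (i in 1:3) {
      d <- delta[i]
      cm <- cf; cm[i] <- cf[i] - d
      cp <- cf; cp[i] <- cf[i] + d
      f0 <- obj(cf); fm <- obj(cm); fp <- obj(cp)
      if (!all(is.finite(c(f0, fm, fp)))) next
      curv <- fp - 2 * f0 + fm
      if (curv > 0) {
        step <- 0.5 * (fm - fp) / curv * d
        cf[i] <- cf[i] + max(min(step, d), -d)
      } else {
        cf[i] <- c(cm[i], cf[i], cp[i])[which.min(c(fm, f0, fp))]
      }
    }
    delta <- delta / 3
  }
  cf
}

# Rotation factor of a near-rigid linear map (polar decomposition via SVD).
polar_rotation <- function(l) {
  sv <- svd(l)
  r <- sv$u %*% t(sv$v)
  if (det(r) < 0) r <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  r
}

# Express a pull-back affine (1-based voxel coords, centre convention of
# me_matrix) approximately as me_params: exact for rigid + axis-aligned
# shear/scale, polar-rotation approximation otherwise.
matrix_to_params <- function(m, dims) {
  l <- m[1:3, 1:3]
  r <- polar_rotation(l)
  s <- t(r) %*% l
  ctr <- (dims + 1) / 2
  tr <- m[1:3, 4] - ctr + l %*% ctr
  # Euler angles of r = Rz Ry Rx
  ry <- asin(pmin(pmax(-r[3, 1], -1), 1))
  rx <- atan2(r[3, 2], r[3, 3])
  rz <- atan2(r[2, 1], r[1, 1])
  me_params(rot = c(rx, ry, rz), trans = as.numeric(tr),
            shear = c(s[2, 1], s[2, 3]), scale_y = s[2, 2])
}

# Register one volume to a reference; returns me_params() vector or NULL on
# failure. Coarse-to-fine: NCC maximized by Nelder-Mead on 2x downsampled
# grids, then refined at full resolution. The search is confined to
# physically plausible motion (|rot| <= 0.2 rad, |trans| <= 5 voxels,
# |shear| <= 0.06, |scale - 1| <= 0.08) by a soft penalty, which excludes
# spurious optima at implausibly large rotations.
register_volume <- function(vol, ref, use_eddy, max_iter = 400, init = NULL,
                            fixed_eddy = NULL, screen_motion = 0) {
  dims <- dim(vol)
  bounds <- c(rep(0.2, 3), rep(5, 3), 0.06, 0.06, 0.08)
  obj <- function(p, volume, reference, dd, scale_t, order) {
    excess <- abs(p) - bounds[seq_along(p)]
    if (any(excess > 0)) return(1 + sum(pmax(excess, 0)))
    pars <- params_unpack(p, use_eddy, scale_t)
    if (!is.null(fixed_eddy)) {
      pars[c("syx", "syz", "sy")] <- fixed_eddy
    }
    m <- me_matrix(pars, dd)
    -ncc(resample_affine(volume, m, order), reference)
  }
  p0 <- init %||% rep(0, if (use_eddy) 9 else 6)
  vol_lo <- downsample2(vol)
  ref_lo <- downsample2(ref)
  fit_lo <- tryCatch(
    stats::optim(p0, obj, volume = vol_lo, reference = ref_lo,
                 dd = dim(vol_lo), scale_t = 0.5, order = 1L,
                 method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = 1e-9,
                                parscale = param_scales(use_eddy))),
    error = function(e) NULL)
  if (is.null(fit_lo)) return(NULL)
  # multi-resolution screen: when both the warm start and the coarse stage
  # show motion well below the detectable threshold, the full-resolution
  # refinement cannot produce a correction that survives the parsimony
  # gate — skip it
  init_small <- is.null(init) ||
    displacement_magnitude(me_params(rot = init[1:3], trans = init[4:6]),
                           dims) < screen_motion
  if (screen_motion > 0 && init_small) {
    coarse <- params_unpack(fit_lo$par, use_eddy, 1)
    if (displacement_magnitude(coarse, dims) < screen_motion)
      return(me_params())
  }
  # full-resolution refinement with shrinking simplex restarts: each restart
  # rebuilds the Nelder-Mead simplex at 30% of the previous scale around the
  # current optimum, escaping premature collapse
  p <- fit_lo$par
  ps <- param_scales(use_eddy)
  for (r in 1:2) {
    fit <- tryCatch(
      stats::optim(p, obj, volume = vol, reference = ref,
                   dd = dims, scale_t = 1, order = 3L, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-12,
                                  parscale = ps)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    p <- fit$par
    ps <- ps * 0.3
  }
  # the NCC surface is extremely flat near its peak; finish with
  # coordinate-wise parabolic steps (exact for a locally quadratic surface)
  f1 <- function(p) obj(p, volume = vol, reference = ref, dd = dims,
                        scale_t = 1, order = 3L)
  delta <- param_scales(use_eddy) * 0.2
  for (sweep in 1:3) {
    for (i in seq_along(p)) {
      d <- delta[i]
      pm <- p; pm[i] <- p[i] - d
      pp <- p; pp[i] <- p[i] + d
      f0 <- f1(p); fm <- f1(pm); fp <- f1(pp)
      if (!all(is.finite(c(f0, fm, fp)))) next
      curv <- fp - 2 * f0 + fm
      if (curv > 0) {
        step <- 0.5 * (fm - fp) / curv * d
        p[i] <- p[i] + max(min(step, d), -d)
      } else {
        p[i] <- c(pm[i], p[i], pp[i])[which.min(c(fm, f0, fp))]
      }
    }
    delta <- delta / 3
  }
  if (!all(is.finite(p))) return(NULL)
  params_unpack(p, use_eddy, 1)
}

# scale_t converts the translation parameters (kept in full-resolution voxel
# units) to the units of the grid being registered (0.5 at the coarse level).
params_unpack <- function(p, use_eddy, scale_t) {
  if (use_eddy)
    me_params(rot = p[1:3], trans = p[4:6] * scale_t,
              shear = p[7:8], scale_y = 1 + p[9])
  else
    me_params(rot = p[1:3], trans = p[4:6] * scale_t)
}

param_scales <- function(use_eddy) {
  s <- c(0.02, 0.02, 0.02, 0.5, 0.5, 0.5)
  if (use_eddy) s <- c(s, 0.02, 0.02, 0.02)
  s
}

# normalized cross-correlation of two arrays (non-finite inputs score worst)
ncc <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  if (!is.finite(ma) || !is.finite(mb)) return(-1)
  av <- as.vector(a) - ma
  bv <- as.vector(b) - mb
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (!is.finite(den) || den == 0) return(0)
  sum(av * bv) / den
}

# 2x block-average downsampling of a 3D array (odd trailing voxels dropped)
downsample2 <- function(vol) {
  d <- dim(vol) %/% 2L
  v <- vol[seq_len(2 * d[1]), seq_len(2 * d[2]), seq_len(2 * d[3]), drop = FALSE]
  i1 <- seq(1, 2 * d[1], 2)
  j1 <- seq(1, 2 * d[2], 2)
  k1 <- seq(1, 2 * d[3], 2)
  (v[i1, j1, k1, drop = FALSE] + v[i1 + 1, j1, k1, drop = FALSE] +
     v[i1, j1 + 1, k1, drop = FALSE] + v[i1, j1, k1 + 1, drop = FALSE] +
     v[i1 + 1, j1 + 1, k1, drop = FALSE] + v[i1 + 1, j1, k1 + 1, drop = FALSE] +
     v[i1, j1 + 1, k1 + 1, drop = FALSE] + v[i1 + 1, j1 + 1, k1 + 1, drop = FALSE]) / 8
}

#' Gaussian smoothing of the diffusion volumes
#'
#' Per-volume 3D Gaussian convolution with SD `sigma` in voxel units,
#' implemented as separable 1D convolutions with reflecting (mirror) boundary
#' handling, which preserves the total signal sum. `sigma = 0` is the
#' identity. Masks/atlases are never smoothed — smoothing feeds model fitting
#' only.
#'
#' @param data A [dwi_dataset()].
#' @param sigma Gaussian SD in voxels (>= 0).
#' @return A [dwi_dataset()].
#' @export
smooth_gaussian <- function(data, sigma) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(data)
  d <- dim(data$signal)
  k1 <- lapply(d[1:3], function(n) gauss_op(n, sigma))
  sig <- matrix(data$signal, d[1], prod(d[2:4]))
  sig <- k1[[1]] %*% sig
  arr <- array(sig, d)
  arr <- aperm(arr, c(2, 1, 3, 4))
  arr <- array(k1[[2]] %*% matrix(arr, d[2], prod(d[c(1, 3, 4)])), d[c(2, 1, 3, 4)])
  arr <- aperm(arr, c(2, 1, 3, 4))
  arr <- aperm(arr, c(3, 2, 1, 4))
  arr <- array(k1[[3]] %*% matrix(arr, d[3], prod(d[c(2, 1, 4)])), d[c(3, 2, 1, 4)])
  arr <- aperm(arr, c(3, 2, 1, 4))
  with_signal(data, arr)
}

# n x n 1D Gaussian convolution operator with mirror (reflect) boundaries
gauss_op <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  op <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in (-r):r) {
      j <- i + k
      # half-sample symmetric reflection
      while (j < 1 || j > n) {
        if (j < 1) j <- 1 - j
        if (j > n) j <- 2 * n + 1 - j
      }
      op[i, j] <- op[i, j] + w[k + r + 1]
    }
  }
  op
}
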