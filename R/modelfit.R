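#' Design matrix for DTI / DKI log-linear fitting
#'
#' One row per volume. DTI columns: intercept (log S0) followed by
#' `-b * mult * n_i n_j` for the 6 unique diffusion-tensor terms
#' (off-diagonal multiplicity 2). DKI appends `(b^2/6) * mult * n_i n_j n_k
#' n_l` for the 15 unique terms of the scaled kurtosis tensor V = MD^2 W
#' (multinomial multiplicities). A b=0 row is (1, 0, ..., 0).
#'
#' @param scheme An [acquisition_scheme()].
#' @param model `"DTI"` or `"DKI"`.
#' @return Matrix with `length(scheme)` rows and 7 (DTI) or 22 (DKI) columns.
#' @export
design_matrix <- function(scheme, model = c("DTI", "DKI")) {
  model <- match.arg(model)
  n <- length(scheme)
  if (model == "DKI") {
    if (!scheme_dki_capable(scheme))
      stopf("DKI needs >= 2 distinct non-zero shells and >= 22 measurements (scheme has %d shells, %d volumes)",
            length(scheme_shells(scheme)), n)
  } else if (n < 7) {
    stopf("DTI needs >= 7 measurements, got %d", n)
  }
  b <- ifelse(scheme_b0(scheme), 0, scheme$bvalues)
  a <- cbind(1, -b * dirprod2_matrix(scheme$directions))
  if (model == "DKI")
    a <- cbind(a, (b^2 / 6) * dirprod4_matrix(scheme$directions))
  a
}

#' Weighted linear least-squares DTI / DKI fit
#'
#' Per voxel: ordinary least squares on log-signals, followed by `iterations`
#' reweighted passes with weights equal to the squared predicted signals (the
#' standard WLLS estimator for log-linearized diffusion models). Signals are
#' clamped to `1e-6 * max(S)` before the log; voxels containing non-positive
#' signals or a singular system are flagged `fit_ok = FALSE` without affecting
#' their neighbours.
#'
#' @param data A [dwi_dataset()].
#' @param model `"DTI"` or `"DKI"`.
#' @param iterations Number of reweighting passes (>= 1; default 2).
#' @param mask Optional 3D logical array restricting the fit.
#' @return A `diffusion_fit`: fields `s0`, `d6` (x,y,z,6; mm^2/s), `v15`
#'   (x,y,z,15; V = MD^2 W, DKI only), `fit_ok` (3D logical), `model`.
#' @export
fit_wlls <- function(data, model = c("DTI", "DKI"), iterations = 2, mask = NULL) {
  model <- match.arg(model)
  if (iterations < 1) stopf("iterations must be >= 1")
  d <- dim(data$signal)
  dims <- d[1:3]
  nvox_all <- prod(dims)
  if (is.null(mask)) mask <- array(TRUE, dims)
  vox <- which(as.vector(mask))

  a <- design_matrix(data$scheme, model)
  p <- ncol(a)
  y <- t(matrix(data$signal, nvox_all, d[4]))[, vox, drop = FALSE]  # nvol x nvox
  ok <- colSums(y <= 0) == 0
  eps <- 1e-6 * max(y)
  y[y < eps] <- eps
  logy <- log(y)

  ata <- crossprod(a)
  coef <- tryCatch(solve(ata, crossprod(a, logy)),
                   error = function(e) stopf("design matrix is singular: %s",
                                             conditionMessage(e)))
  # row-wise outer products of design rows, for batched weighted normal eqs
  bouter <- t(apply(a, 1, function(r) as.vector(outer(r, r))))  # nvol x p^2
  for (it in seq_len(iterations)) {
    w <- exp(2 * (a %*% coef))               # nvol x nvox: predicted signal^2
    w <- pmin(w, 1e300)
    lhs <- crossprod(w, bouter)              # nvox x p^2
    rhs <- crossprod(w * logy, a)            # nvox x p
    sol <- wlls_solve_cpp(lhs, rhs)
    good <- sol$ok
    coef[, good] <- sol$coef[, good, drop = FALSE]
    ok <- ok & good
  }

  s0 <- array(NA_real_, dims)
  s0[vox] <- exp(coef[1, ])
  d6m <- matrix(NA_real_, nvox_all, 6)
  d6m[vox, ] <- t(coef[2:7, , drop = FALSE])
  fit_ok <- array(FALSE, dims)
  fit_ok[vox] <- ok
  out <- list(s0 = s0, d6 = array(d6m, c(dims, 6)), v15 = NULL,
              fit_ok = fit_ok, model = model)
  if (model == "DKI") {
    v15m <- matrix(NA_real_, nvox_all, 15)
    v15m[vox, ] <- t(coef[8:22, , drop = FALSE])
    out$v15 <- array(v15m, c(dims, 15))
  }
  structure(out, class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit (%s): %s, %d voxels fit_ok>\n", x$model,
              paste(dim(x$s0), collapse = " x "), sum(x$fit_ok)))
  invisible(x)
}

#' Scalar parameter maps from a diffusion fit
#'
#' Eigendecomposes the fitted tensor per voxel (eigenvalues clamped at 0,
#' sorted descending) and derives: FA = sqrt(3/2) sqrt(sum((l - lbar)^2) /
#' sum(l^2)), MD = mean(l), AD = l1, RD = (l2 + l3)/2. For DKI fits the
#' apparent kurtosis K_app(n) = V_app(n) / D_app(n)^2 (with V = MD^2 W the
#' fitted scaled kurtosis tensor) gives MK (mean of K_app over
#' `direction_set`), AK (K_app along the principal eigenvector) and RK (mean
#' of K_app over directions orthogonal to it). Kurtosis values are clipped to
#' `kurtosis_range`.
#'
#' @param fit A `diffusion_fit` from [fit_wlls()].
#' @param direction_set Matrix of unit vectors for the MK average (>= 60
#'   near-uniform directions; default 64-point spherical Fibonacci set).
#' @param kurtosis_range Reporting range for MK/AK/RK.
#' @param n_radial Number of in-plane directions for the RK average.
#' @return A `scalar_maps` object: 3D arrays `fa`, `md`, `ad`, `rd` (and
#'   `mk`, `ak`, `rk` for DKI), plus `fit_ok`.
#' @export
scalar_metrics <- function(fit, direction_set = kurtosis_dirs(64),
                           kurtosis_range = c(-2, 10), n_radial = 16) {
  dims <- dim(fit$s0)
  vox <- which(fit$fit_ok)
  nv <- length(vox)
  dki <- !is.null(fit$v15)
  d6m <- matrix(fit$d6, prod(dims), 6)[vox, , drop = FALSE]
  fa <- md <- ad <- rd <- array(NA_real_, dims)
  if (dki) mk <- ak <- rk <- array(NA_real_, dims)
  if (dki) {
    v15m <- matrix(fit$v15, prod(dims), 15)[vox, , drop = FALSE]
    vapp_mk <- apparent_w(v15m, direction_set)
    dapp_mk <- apparent_diffusivity(d6m, direction_set)
    kapp <- vapp_mk / pmax(dapp_mk, 1e-12)^2
    mk_v <- rowMeans(kapp)
  }
  phi <- 2 * pi * (seq_len(n_radial) - 1) / n_radial
  clip <- function(x) pmin(pmax(x, kurtosis_range[1]), kurtosis_range[2])
  n_clipped <- 0L

  lam <- matrix(0, nv, 3)
  e1m <- matrix(0, nv, 3)
  for (i in seq_len(nv)) {
    eg <- eigen(d6_to_mat(d6m[i, ]), symmetric = TRUE)
    lam[i, ] <- eg$values
    e1m[i, ] <- eg$vectors[, 1]
  }
  lam <- pmax(lam, 0)
  md_v <- rowMeans(lam)
  ad_v <- lam[, 1]
  rd_v <- (lam[, 2] + lam[, 3]) / 2
  ssq <- rowSums(lam^2)
  dev <- rowSums((lam - md_v)^2)
  fa_v <- ifelse(ssq > 0, sqrt(3 / 2) * sqrt(dev / ssq), 0)
  if (dki) {
    ak_v <- rowSums(dirprod4_matrix(e1m) * v15m) / pmax(ad_v, 1e-12)^2
    # orthonormal in-plane frame per voxel
    use_x <- abs(e1m[, 1]) < 0.9
    h <- cbind(ifelse(use_x, 1, 0), ifelse(use_x, 0, 1), 0)
    dot <- rowSums(h * e1m)
    u2 <- h - dot * e1m
    u2 <- u2 / sqrt(rowSums(u2^2))
    u3 <- cbind(e1m[, 2] * u2[, 3] - e1m[, 3] * u2[, 2],
                e1m[, 3] * u2[, 1] - e1m[, 1] * u2[, 3],
                e1m[, 1] * u2[, 2] - e1m[, 2] * u2[, 1])
    kacc <- numeric(nv)
    for (a in phi) {
      n <- cos(a) * u2 + sin(a) * u3
      vapp <- rowSums(dirprod4_matrix(n) * v15m)
      dapp <- rowSums(dirprod2_matrix(n) * d6m)
      kacc <- kacc + vapp / pmax(dapp, 1e-12)^2
    }
    rk_v <- kacc / n_radial
  }
  fa[vox] <- pmin(fa_v, 1)
  md[vox] <- md_v; ad[vox] <- ad_v; rd[vox] <- rd_v
  out <- list(fa = fa, md = md, ad = ad, rd = rd, fit_ok = fit$fit_ok,
              model = fit$model)
  if (dki) {
    raw <- c(mk_v, ak_v, rk_v)
    n_clipped <- sum(raw < kurtosis_range[1] | raw > kurtosis_range[2])
    if (n_clipped > 0)
      message(sprintf("scalar_metrics: clipped %d of %d kurtosis values to [%g, %g]",
                      n_clipped, length(raw), kurtosis_range[1], kurtosis_range[2]))
    mk[vox] <- clip(mk_v); ak[vox] <- clip(ak_v); rk[vox] <- clip(rk_v)
    out$mk <- mk; out$ak <- ak; out$rk <- rk
  }
  structure(out, class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  pars <- intersect(c("fa", "md", "ad", "rd", "mk", "ak", "rk"), names(x))
  cat(sprintf("<scalar_maps (%s): %s; parameters %s>\n", x$model,
              paste(dim(x$fa), collapse = " x "), paste(pars, collapse = ", ")))
  invisible(x)
}

#' Parameters available in a scalar map set
#' @param maps A `scalar_maps` object.
#' @return Character vector of parameter names.
#' @export
map_parameters <- function(maps) {
  intersect(c("fa", "md", "ad", "rd", "mk", "ak", "rk"), names(maps))
}
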