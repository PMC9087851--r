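#' Sample one subject's tissue model from a population
#'
#' Draws per-tract mean parameters from the group distribution (patients are
#' shifted by `designed_d * between_subject_sd` in the affected tracts), builds
#' voxelwise diffusion and kurtosis tensors with the principal axis along the
#' local tract orientation, and mixes overlapping tracts and background by
#' probability weight (partial volume). Background tissue is nearly isotropic
#' (FA 0.10, MD 0.90e-3 mm^2/s, MK 0.6). Deterministic given `seed`.
#'
#' @param pop A [population_spec()].
#' @param atlas A [tract_atlas()].
#' @param group `"HC"` or `"SLE"`.
#' @param seed Integer seed for this subject.
#' @return An object of class `tissue_model`: fields `s0` (3D), `d6`
#'   (x,y,z,6 diffusion tensor, mm^2/s), `w15` (x,y,z,15 kurtosis tensor),
#'   `mask` (3D logical brain mask) and `truth` (tibble of per-tract drawn
#'   means).
#' @export
sample_subject <- function(pop, atlas, group = c("HC", "SLE"), seed = 1L) {
  group <- match.arg(group)
  known <- c(atlas$tract_names, unique(merged_tracts(atlas)$merged))
  missing_tr <- setdiff(pop$affected_tracts, known)
  if (length(missing_tr))
    stopf("affected tracts not in atlas: %s", paste(missing_tr, collapse = ", "))
  base <- tract_baselines(pop, atlas)
  nt <- n_tracts(atlas)

  withr::local_seed(seed)
  draw <- base
  # one between-subject deviation per merged (left/right-averaged) tract:
  # hemispheric homologues are strongly correlated within a subject, and the
  # designed effect size is defined on the merged tract means
  stem <- merged_tracts(atlas)$merged
  ms <- unique(stem)
  idx <- match(stem, ms)
  dev <- function(sd) stats::rnorm(length(ms), 0, sd)[idx]
  draw$fa <- base$fa + dev(pop$between_subject_sd[["fa"]])
  draw$md <- base$md + dev(pop$between_subject_sd[["md"]])
  draw$mk <- base$mk + dev(pop$between_subject_sd[["mk"]])
  if (group == "SLE" && length(pop$affected_tracts)) {
    hit <- draw$tract %in% pop$affected_tracts | stem %in% pop$affected_tracts
    shift <- pop$direction * pop$designed_d * pop$between_subject_sd[[pop$parameter]]
    draw[[pop$parameter]][hit] <- draw[[pop$parameter]][hit] + shift
  }
  draw$fa <- pmin(pmax(draw$fa, 0.05), 0.95)
  draw$md <- pmax(draw$md, 1e-4)

  dims <- dim(atlas$prob)[1:3]
  mask <- brain_mask(dims)

  axes <- atlas_axes(atlas)
  # per-tract lab-frame tensors
  d6_t <- matrix(0, nt, 6)
  w15_t <- matrix(0, nt, 15)
  for (t in seq_len(nt)) {
    ax <- axes[t, ]
    fr <- frame_from_axis(ax)
    eig <- eigs_from_fa_md(draw$fa[t], draw$md[t])
    d6_t[t, ] <- mat_to_d6(fr %*% diag(eig) %*% t(fr))
    w15_t[t, ] <- w15_from_kurtosis(draw$mk[t], draw$ak[t], draw$rk[t], eig, fr)
  }
  # background tissue: nearly isotropic, with its own between-subject
  # variability (global physiology differs across subjects), so partial
  # volume with background dilutes tract effects with unrelated variance
  bg_fa <- min(max(0.10 + stats::rnorm(1, 0, 0.015), 0.02), 0.3)
  bg_md <- max(0.90e-3 + stats::rnorm(1, 0, 0.03e-3), 3e-4)
  bg_eig <- eigs_from_fa_md(bg_fa, bg_md)
  bg_fr <- diag(3)
  d6_bg <- mat_to_d6(bg_fr %*% diag(bg_eig) %*% t(bg_fr))
  w15_bg <- w15_from_kurtosis(0.6, 0.6, 0.6, bg_eig, bg_fr)

  nvox <- prod(dims)
  pmat <- matrix(atlas$prob, nvox, nt)     # voxel x tract weights
  wsum <- rowSums(pmat)
  scale_over <- ifelse(wsum > 1, 1 / wsum, 1)
  pmat <- pmat * scale_over
  wbg <- pmax(0, 1 - rowSums(pmat))

  d6 <- pmat %*% d6_t + outer(wbg, d6_bg)
  w15 <- pmat %*% w15_t + outer(wbg, w15_bg)
  d6[!mask, ] <- 0
  w15[!mask, ] <- 0
  # white matter has lower baseline signal than surrounding tissue (shorter
  # T2), which also gives b=0 volumes registration-relevant structure; the
  # brain edge falls off smoothly (no step edge, as in real magnitude
  # images); a smooth per-subject intensity texture emulates the anatomical
  # heterogeneity that makes real brains registrable in every direction
  env <- as.vector(brain_envelope(dims))
  tex <- as.vector(texture_field(dims, sd_rel = 0.12, sigma = 1.5))
  s0 <- ifelse(as.vector(mask),
               pop$s0 * (1 - 0.15 * rowSums(pmat)) * env * tex, 0)

  structure(
    list(s0 = array(s0, dims),
         d6 = array(d6, c(dims, 6)),
         w15 = array(w15, c(dims, 15)),
         mask = mask,
         truth = dplyr::mutate(draw, group = group, seed = seed)),
    class = "tissue_model"
  )
}

# Smooth multiplicative intensity texture: Gaussian-filtered white noise,
# rescaled to relative SD `sd_rel` around 1. Drawn from the current RNG
# stream, so it is subject-specific but seed-reproducible.
texture_field <- function(dims, sd_rel = 0.12, sigma = 1.5) {
  raw <- array(stats::rnorm(prod(dims)), dims)
  k <- lapply(dims, function(n) gauss_op(n, sigma))
  sm <- matrix(raw, dims[1], prod(dims[2:3]))
  sm <- k[[1]] %*% sm
  arr <- array(sm, dims)
  arr <- aperm(arr, c(2, 1, 3))
  arr <- array(k[[2]] %*% matrix(arr, dims[2], prod(dims[c(1, 3)])), dim = dims[c(2, 1, 3)])
  arr <- aperm(arr, c(2, 1, 3))
  arr <- aperm(arr, c(3, 2, 1))
  arr <- array(k[[3]] %*% matrix(arr, dims[3], prod(dims[c(2, 1)])), dim = dims[c(3, 2, 1)])
  arr <- aperm(arr, c(3, 2, 1))
  arr <- arr / stats::sd(arr)
  pmax(1 + sd_rel * arr, 0.2)
}

# Smooth radial signal envelope: ~1 deep inside the brain ellipsoid,
# decaying to ~0 before the mask boundary (logistic in normalized radius).
brain_envelope <- function(dims) {
  cx <- (dims + 1) / 2
  semi <- (dims - 2) / 2
  gx <- ((seq_len(dims[1]) - cx[1]) / semi[1])^2
  gy <- ((seq_len(dims[2]) - cx[2]) / semi[2])^2
  gz <- ((seq_len(dims[3]) - cx[3]) / semi[3])^2
  r <- sqrt(outer(outer(gx, gy, "+"), gz, "+"))
  array(stats::plogis((0.8 - r) / 0.05), dims)
}

# Ellipsoidal brain mask inscribed in the grid with a small margin.
brain_mask <- function(dims) {
  cx <- (dims + 1) / 2
  semi <- (dims - 2) / 2
  gx <- ((seq_len(dims[1]) - cx[1]) / semi[1])^2
  gy <- ((seq_len(dims[2]) - cx[2]) / semi[2])^2
  gz <- ((seq_len(dims[3]) - cx[3]) / semi[3])^2
  array(outer(outer(gx, gy, "+"), gz, "+") <= 1, dims)
}

# Per-tract dominant orientations, cached on the atlas in the calling frame's
# copy (cheap to recompute; cached per process via the environment below).
atlas_axes <- local({
  cache <- list()
  function(atlas) {
    key <- rlang::hash(atlas$prob)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ax <- t(vapply(seq_len(n_tracts(atlas)), function(t) tract_axis(atlas, t),
                   numeric(3)))
    cache[[key]] <<- ax
    ax
  }
})

# Dominant orientation of a tract: principal axis of its probability-weighted
# voxel coordinate covariance.
tract_axis <- function(atlas, t) {
  p <- atlas$prob[, , , t]
  idx <- which(p > 0.05, arr.ind = TRUE)
  if (nrow(idx) < 4) return(c(1, 0, 0))
  w <- p[idx]
  mu <- colSums(idx * w) / sum(w)
  xc <- sweep(idx, 2, mu)
  cv <- crossprod(xc * sqrt(w / sum(w)))
  eigen(cv, symmetric = TRUE)$vectors[, 1]
}

#' @export
print.tissue_model <- function(x, ...) {
  d <- dim(x$s0)
  cat(sprintf("<tissue_model: %d x %d x %d, %d brain voxels>\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}
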