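#' Tract probability atlas
#'
#' Per-tract probability maps on a common grid, with tract names and a
#' laterality table linking left/right homologues. Probabilities must lie in
#' [0, 1] (a tolerance of 1e-6 is clipped). Tracts whose names end in
#' `_left` / `_right` are paired automatically when no explicit pairing is
#' given; pairing is symmetric (an involution).
#'
#' @param probabilities 4D array (x, y, z, tract) of membership probabilities.
#' @param tract_names Character vector of tract names.
#' @param laterality Optional character vector in `c("left","right","midline")`;
#'   inferred from name suffixes when `NULL`.
#' @param pair Optional character vector naming each tract's partner
#'   (`NA` for midline).
#' @return An object of class `tract_atlas` with fields `prob`, `tract_names`
#'   and `laterality` (a tibble: `tract`, `side`, `pair`, `empty`).
#' @export
tract_atlas <- function(probabilities, tract_names, laterality = NULL, pair = NULL) {
  prob <- as.array(probabilities)
  if (length(dim(prob)) != 4)
    stopf("probabilities must be 4D (x, y, z, tract)")
  n <- dim(prob)[4]
  if (n != length(tract_names))
    stopf("%d maps but %d tract names", n, length(tract_names))
  if (n > 72) stopf("tract count %d exceeds 72", n)
  rng <- range(prob)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    stopf("probability values outside [0, 1]: range %.4g .. %.4g", rng[1], rng[2])
  prob[prob < 0] <- 0
  prob[prob > 1] <- 1

  if (is.null(laterality)) {
    laterality <- dplyr::case_when(
      grepl("_left$", tract_names) ~ "left",
      grepl("_right$", tract_names) ~ "right",
      TRUE ~ "midline"
    )
  }
  if (is.null(pair)) {
    stem <- sub("_(left|right)$", "", tract_names)
    pair <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (laterality[i] == "midline") next
      other <- if (laterality[i] == "left") "right" else "left"
      cand <- paste0(stem[i], "_", other)
      if (cand %in% tract_names) pair[i] <- cand
    }
  }
  # pairing must be symmetric
  for (i in seq_len(n)) {
    if (is.na(pair[i])) next
    j <- match(pair[i], tract_names)
    if (is.na(j)) stopf("tract '%s' pairs to unknown tract '%s'", tract_names[i], pair[i])
    if (!identical(pair[j], tract_names[i]))
      stopf("pairing is not symmetric for '%s' / '%s'", tract_names[i], pair[i])
  }
  empty <- apply(prob, 4, function(m) all(m == 0))
  structure(
    list(prob = prob,
         tract_names = tract_names,
         laterality = tibble::tibble(tract = tract_names, side = laterality,
                                     pair = pair, empty = empty)),
    class = "tract_atlas"
  )
}

#' @export
print.tract_atlas <- function(x, ...) {
  d <- dim(x$prob)
  np <- sum(!is.na(x$laterality$pair)) / 2
  cat(sprintf("<tract_atlas: %d tracts on %d x %d x %d (%d L/R pairs, %d midline)>\n",
              d[4], d[1], d[2], d[3], np, sum(is.na(x$laterality$pair))))
  invisible(x)
}

#' Number of tracts in an atlas
#' @param atlas A `tract_atlas`.
#' @return Integer count.
#' @export
n_tracts <- function(atlas) dim(atlas$prob)[4]

# Merged-tract table: one row per L/R pair or midline tract.
merged_tracts <- function(atlas) {
  lat <- atlas$laterality
  stem <- ifelse(is.na(lat$pair), lat$tract, sub("_(left|right)$", "", lat$tract))
  tibble::tibble(tract = lat$tract, merged = stem)
}

#' Generate a synthetic tract atlas
#'
#' Builds smooth tube-shaped probability maps (quadratic space curves with a
#' Gaussian cross-sectional profile and soft edges) on a cubic grid. An even
#' subset of tracts is laid down as mirrored left/right pairs about the
#' mid-sagittal plane; the remainder are midline tracts. Deterministic given
#' `seed`.
#'
#' @param grid_shape Integer length-3 grid size, each >= 16.
#' @param n_tracts Number of tracts (>= 2). Pairs are formed from the first
#'   `2 * floor(n_tracts / 3)` tracts (rounded down to an even count).
#' @param seed Integer seed.
#' @param radius Tube radius in voxels (Gaussian sigma of the profile).
#' @return A [tract_atlas()] with names `tract01_left`, `tract01_right`,
#'   `tract03`, ... reflecting pairing.
#' @export
build_atlas <- function(grid_shape, n_tracts, seed, radius = 1.6) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3)
  if (any(grid_shape < 16)) stopf("grid must be at least 16 in every dimension")
  if (n_tracts < 1) stopf("n_tracts must be >= 1")
  # each tube claims roughly (4 radius)^2 * extent voxels; refuse absurd packing
  if (n_tracts * 16 * radius^2 > 4 * prod(grid_shape[1:2]))
    stopf("cannot pack %d tracts into a %s grid", n_tracts,
          paste(grid_shape, collapse = "x"))

  n_pairs <- floor(n_tracts / 3)
  if (2 * n_pairs > n_tracts) n_pairs <- n_pairs - 1
  n_pairs <- max(0L, n_pairs)
  n_mid <- n_tracts - 2L * n_pairs

  withr::local_seed(seed)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  prob <- array(0, c(grid_shape, n_tracts))
  names_out <- character(n_tracts)
  side <- character(n_tracts)
  pair <- rep(NA_character_, n_tracts)

  # control points for one tube within a box [lo, hi] per axis
  sample_curve <- function(xr, yr, zr) {
    p <- function() c(stats::runif(1, xr[1], xr[2]),
                      stats::runif(1, yr[1], yr[2]),
                      stats::runif(1, zr[1], zr[2]))
    list(a = p(), b = p(), c = p())
  }

  tube_map <- function(curve) {
    tt <- seq(0, 1, length.out = 2 * max(grid_shape))
    # quadratic Bezier
    pts <- outer((1 - tt)^2, curve$a) + outer(2 * tt * (1 - tt), curve$b) +
      outer(tt^2, curve$c)
    m <- array(Inf, grid_shape)
    gx <- seq_len(nx); gy <- seq_len(ny); gz <- seq_len(nz)
    # distance to polyline, evaluated on the grid slab near the curve
    for (k in seq_len(nrow(pts))) {
      p <- pts[k, ]
      dx2 <- (gx - p[1])^2
      dy2 <- (gy - p[2])^2
      dz2 <- (gz - p[3])^2
      lo <- pmax(1, floor(p - 4 * radius)); hi <- pmin(grid_shape, ceiling(p + 4 * radius))
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      d2 <- outer(outer(dx2[ix], dy2[iy], "+"), dz2[iz], "+")
      m[ix, iy, iz] <- pmin(m[ix, iy, iz], d2)
    }
    p <- exp(-m / (2 * radius^2))
    p[p < 0.01] <- 0
    pmin(p, 1)
  }

  mirror_x <- function(m) m[rev(seq_len(nx)), , , drop = FALSE]

  k <- 1L
  margin <- 3
  for (ip in seq_len(n_pairs)) {
    # left-hemisphere tube (x below the mid-sagittal plane), mirrored for right
    curve <- sample_curve(c(margin, nx / 2 - 2), c(margin, ny - margin),
                          c(margin, nz - margin))
    mL <- tube_map(curve)
    base <- sprintf("tract%02d", k)
    prob[, , , k] <- mL
    names_out[k] <- paste0(base, "_left"); side[k] <- "left"
    prob[, , , k + 1L] <- mirror_x(mL)
    names_out[k + 1L] <- paste0(base, "_right"); side[k + 1L] <- "right"
    pair[k] <- names_out[k + 1L]; pair[k + 1L] <- names_out[k]
    k <- k + 2L
  }
  for (im in seq_len(n_mid)) {
    curve <- sample_curve(c(nx / 2 - 4, nx / 2 + 4), c(margin, ny - margin),
                          c(margin, nz - margin))
    prob[, , , k] <- tube_map(curve)
    names_out[k] <- sprintf("tract%02d", k); side[k] <- "midline"
    k <- k + 1L
  }
  tract_atlas(prob, names_out, laterality = side, pair = pair)
}
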