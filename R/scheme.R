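#' Diffusion acquisition scheme
#'
#' An acquisition scheme is the per-volume table of diffusion weightings
#' (b-values, s/mm\eqn{^2}) and unit encoding directions, together with the
#' isotropic voxel size and timing metadata. b-values at or below `b0_max`
#' (default 50 s/mm\eqn{^2}) are treated as unweighted baseline (b=0) volumes;
#' their direction may be the zero vector.
#'
#' @param bvalues Numeric vector, one b-value per volume (s/mm^2).
#' @param directions 3-column matrix (or N x 3) of encoding directions, one row
#'   per volume. Rows for b > 0 volumes must have unit norm (renormalized when
#'   within 1e-3 of 1); b = 0 rows may be zero.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param name Label for the scheme.
#' @param te_ms,tr_ms Echo/repetition time in ms (metadata only).
#' @return An object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(bvalues, directions, voxel_size,
                               name = "custom", te_ms = NA_real_, tr_ms = NA_real_) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3 && nrow(directions) == 3) directions <- t(directions)
  if (ncol(directions) != 3)
    stopf("directions must be an N x 3 matrix")
  dimnames(directions) <- NULL
  if (length(bvalues) != nrow(directions))
    stopf("scheme length %d != direction count %d", length(bvalues), nrow(directions))
  nrm <- sqrt(rowSums(directions^2))
  dwi <- bvalues > b0_max()
  bad <- dwi & abs(nrm - 1) >= 1e-3
  if (any(bad))
    stopf("%d diffusion-weighted directions deviate from unit norm by >= 1e-3", sum(bad))
  fix <- dwi & abs(nrm - 1) > 1e-12
  directions[fix, ] <- directions[fix, , drop = FALSE] / nrm[fix]
  if (!any(!dwi))
    stopf("scheme has no b=0 volume (b <= %g)", b0_max())
  structure(
    list(name = name, bvalues = bvalues, directions = directions,
         voxel_size = as.numeric(voxel_size), te_ms = te_ms, tr_ms = tr_ms),
    class = "acquisition_scheme"
  )
}

# b-values at or below this count as b=0 (scanners report small nonzero b).
b0_max <- function() 50

#' @export
length.acquisition_scheme <- function(x) length(x$bvalues)

#' Indices / mask of b=0 volumes in a scheme
#' @param scheme An `acquisition_scheme`.
#' @return `scheme_b0()` a logical mask; `scheme_shells()` the sorted distinct
#'   non-zero b-values.
#' @export
scheme_b0 <- function(scheme) scheme$bvalues <= b0_max()

#' @rdname scheme_b0
#' @export
scheme_shells <- function(scheme) sort(unique(scheme$bvalues[!scheme_b0(scheme)]))

#' Is a scheme capable of supporting a kurtosis (DKI) fit?
#'
#' Requires at least two distinct non-zero shells and at least 22 measurements.
#' @param scheme An `acquisition_scheme`.
#' @return Logical.
#' @export
scheme_dki_capable <- function(scheme) {
  length(scheme_shells(scheme)) >= 2 && length(scheme) >= 22
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  b0 <- sum(scheme_b0(x))
  sh <- scheme_shells(x)
  cnt <- vapply(sh, function(b) sum(x$bvalues == b), integer(1))
  cat(sprintf("<acquisition_scheme '%s': %d volumes, %.1f mm>\n", x$name, length(x), x$voxel_size))
  cat(sprintf("  b = 0 (%d)%s\n", b0,
              if (length(sh)) paste0(", ", paste(sprintf("%g (%d)", sh, cnt), collapse = ", ")) else ""))
  invisible(x)
}

#' Study acquisition protocols
#'
#' Returns one of the three acquisition protocols of the benchmark study:
#' \describe{
#'   \item{`3T-DTI`}{2.0 mm isotropic; b = 0 (8), 1000 (64); TR/TE 7300/73 ms.}
#'   \item{`3T-DKI`}{2.3 mm isotropic; b = 0 (3), 250 (6), 500 (6), 1000 (20),
#'     2750 (30); TR/TE 7500/103 ms.}
#'   \item{`7T-DTI`}{2.0 mm isotropic; b = 0 (3), 1000 (30); TR/TE 8816/62 ms.}
#' }
#' Directions per shell are near-uniform deterministic hemisphere designs.
#'
#' @param name Protocol name.
#' @param n_directions Optional reduced number of directions for the highest
#'   shell (direction-subsampling experiments); `NULL` keeps the full protocol.
#' @return An `acquisition_scheme`.
#' @export
protocol_scheme <- function(name = c("3T-DTI", "3T-DKI", "7T-DTI"),
                            n_directions = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    "3T-DTI" = list(shells = c(0, 1000), counts = c(8, 64), vox = 2.0, te = 73, tr = 7300),
    "3T-DKI" = list(shells = c(0, 250, 500, 1000, 2750), counts = c(3, 6, 6, 20, 30),
                    vox = 2.3, te = 103, tr = 7500),
    "7T-DTI" = list(shells = c(0, 1000), counts = c(3, 30), vox = 2.0, te = 62, tr = 8816)
  )
  if (!is.null(n_directions)) {
    spec$counts[length(spec$counts)] <- as.integer(n_directions)
  }
  bv <- rep(spec$shells, spec$counts)
  dirs <- matrix(0, length(bv), 3)
  for (i in seq_along(spec$shells)[-1]) {
    idx <- which(bv == spec$shells[i])
    # rotate each shell's lattice slightly so shells do not share directions
    d <- hemisphere_dirs(length(idx))
    ang <- (i - 1) * 0.31
    rot <- rotation_matrix(c(ang, ang / 2, ang / 3))
    dirs[idx, ] <- d %*% t(rot)
  }
  acquisition_scheme(bv, dirs, spec$vox, name = name, te_ms = spec$te, tr_ms = spec$tr)
}

# Rotation matrix from intrinsic x-y-z Euler angles (radians).
rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}
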