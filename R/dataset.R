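#' One subject's diffusion-weighted dataset
#'
#' Couples a 4D signal array (x, y, z, volume) with its acquisition scheme,
#' voxel-to-world affine and subject metadata. The 4th dimension must match the
#' scheme length; signals must be finite and non-negative.
#'
#' @param signal 4D numeric array (x, y, z, volume).
#' @param scheme An [acquisition_scheme()].
#' @param affine 4x4 voxel-to-world transform; default diagonal from the
#'   scheme's voxel size.
#' @param subject_id,group Subject label and group label (e.g. "HC", "SLE").
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, scheme, affine = NULL,
                        subject_id = "subj", group = NA_character_) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4)
    stopf("signal must be a 4D array, got %d dims", length(dim(signal)))
  if (dim(signal)[4] != length(scheme))
    stopf("scheme length %d != volume count %d", length(scheme), dim(signal)[4])
  nbad <- sum(!is.finite(signal))
  if (nbad > 0) stopf("signal contains %d non-finite voxels", nbad)
  if (is.null(affine)) {
    affine <- diag(c(rep(scheme$voxel_size, 3), 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stopf("affine must be an invertible 4x4 matrix")
  structure(
    list(signal = signal, scheme = scheme, affine = affine,
         subject_id = subject_id, group = group),
    class = "dwi_dataset"
  )
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_dataset '%s' (%s): %d x %d x %d x %d, scheme '%s'>\n",
              x$subject_id, x$group, d[1], d[2], d[3], d[4], x$scheme$name))
  invisible(x)
}

#' @export
dim.dwi_dataset <- function(x) dim(x$signal)

# Replace the signal array, keeping metadata.
with_signal <- function(data, signal) {
  data$signal <- signal
  data
}
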