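#' Read a diffusion dataset from NIfTI + FSL bvals/bvecs
#'
#' Reads a 4D NIfTI-1 volume together with FSL-dialect gradient tables: a
#' `bval` file holding one whitespace-separated row of b-values and a `bvec`
#' file holding three rows (x, y, z components, image axes). Directions whose
#' norm deviates from 1 by less than 1e-3 are renormalized.
#'
#' @param path_nii Path to the 4D NIfTI file (.nii or .nii.gz).
#' @param path_bval,path_bvec Paths to the FSL bvals/bvecs text files.
#' @param voxel_size Override for the isotropic voxel size; by default taken
#'   from the NIfTI header (first pixel dimension).
#' @param subject_id,group Subject metadata labels.
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(path_nii, path_bval, path_bvec, voxel_size = NULL,
                     subject_id = "subj", group = NA_character_) {
  img <- RNifti::readNifti(path_nii)
  arr <- as.array(img)
  if (length(dim(arr)) != 4)
    stopf("expected a 4D NIfTI, got %d dims", length(dim(arr)))
  bval <- scan(path_bval, what = numeric(), quiet = TRUE)
  bvec <- as.matrix(utils::read.table(path_bvec))
  if (nrow(bvec) != 3)
    stopf("bvec file must have three rows, got %d", nrow(bvec))
  if (length(bval) != dim(arr)[4])
    stopf("scheme length %d != volume count %d", length(bval), dim(arr)[4])
  if (ncol(bvec) != length(bval))
    stopf("bvec has %d columns but bval has %d entries", ncol(bvec), length(bval))
  vs <- voxel_size %||% RNifti::pixdim(img)[1]
  scheme <- acquisition_scheme(bval, t(bvec), voxel_size = vs,
                               name = basename(path_nii))
  affine <- structure(RNifti::xform(img), class = "matrix")[seq_len(4), seq_len(4)]
  dwi_dataset(arr, scheme, affine = affine, subject_id = subject_id, group = group)
}

#' Write a diffusion dataset to NIfTI + bvals/bvecs
#'
#' Inverse of [read_dwi()]: values round-trip exactly (float64 storage), the
#' scheme to text precision.
#'
#' @param data A [dwi_dataset()].
#' @param path_nii,path_bval,path_bvec Output paths.
#' @return `path_nii`, invisibly.
#' @export
write_dwi <- function(data, path_nii, path_bval, path_bvec) {
  arr <- data$signal
  attr(arr, "pixdim") <- rep(data$scheme$voxel_size, 4)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path_nii)
  writeLines(paste(format(data$scheme$bvalues, trim = TRUE), collapse = " "), path_bval)
  bv <- t(data$scheme$directions)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), path_bvec)
  invisible(path_nii)
}

#' Read a tract probability atlas
#'
#' Reads a 4D probability NIfTI (x, y, z, tract) plus a names TSV with columns
#' `name`, and optionally `laterality` and `pair`. When the `pair` column is
#' absent, left/right pairs are resolved from `_left` / `_right` name suffixes.
#'
#' @param path_nii Path to the 4D probability NIfTI.
#' @param path_names Path to the names TSV.
#' @return A [tract_atlas()].
#' @export
read_atlas <- function(path_nii, path_names) {
  arr <- as.array(RNifti::readNifti(path_nii))
  if (length(dim(arr)) != 4)
    stopf("atlas NIfTI must be 4D, got %d dims", length(dim(arr)))
  nm <- readr::read_tsv(path_names, show_col_types = FALSE)
  if (!"name" %in% names(nm)) stopf("names table must have a 'name' column")
  if (dim(arr)[4] != nrow(nm))
    stopf("atlas has %d maps but names table %d rows", dim(arr)[4], nrow(nm))
  tract_atlas(arr, nm$name,
              laterality = if ("laterality" %in% names(nm)) nm$laterality else NULL,
              pair = if ("pair" %in% names(nm)) nm$pair else NULL)
}

#' Write per-tract statistics with a run manifest
#'
#' Writes a TSV with stable column order ('.' decimal separator, UTF-8) and a
#' JSON run manifest (seed, config hash, package version, timestamp) alongside
#' it at `<path>.manifest.json`.
#'
#' @param rows A data frame of statistics.
#' @param path Output TSV path.
#' @param seed,config Optional: recorded in the manifest; `config` is hashed.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(rows, path, seed = NULL, config = NULL) {
  lead <- intersect(c("protocol", "pipeline", "sigma", "tract", "parameter",
                      "feature", "statistic"), names(rows))
  rows <- dplyr::relocate(tibble::as_tibble(rows), dplyr::all_of(lead))
  readr::write_tsv(rows, path)
  manifest <- list(
    seed = seed,
    config_hash = if (is.null(config)) NULL else
      rlang::hash(config),
    package = "tractsens",
    version = as.character(utils::packageVersion("tractsens")),
    n_rows = nrow(rows),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with fields `protocols`, `pipelines`,
#'   `smoothing_sigmas`, `seed`, `group_sizes`, `thresholds`.
#' @return A `study_config` list (see [study_config()]).
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}
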