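#' Probability-weighted per-tract statistics
#'
#' For each tract and parameter map: voxels with tract probability below
#' `prob_floor` (default 0.5) are excluded entirely; over the remaining
#' voxels the probability-weighted mean `sum(p x) / sum(p)` and weighted SD
#' `sqrt(sum(p (x - mean)^2) / sum(p))` (population form; set
#' `weighted_sd = FALSE` for the unweighted SD) are computed. Both mean and
#' SD are emitted as separate features, since either can carry group
#' information.
#'
#' @param maps A `scalar_maps` object from [scalar_metrics()].
#' @param atlas A [tract_atlas()] on the same grid.
#' @param prob_floor Probability threshold below which voxels are excluded.
#' @param weighted_sd Use probability weights in the SD (default TRUE).
#' @param subject_id,group Metadata columns for the output.
#' @return A tibble with columns `subject_id`, `group`, `tract`, `parameter`,
#'   `feature` (`"mean"`/`"sd"`), `value`, `n_voxels`. Tracts with no
#'   qualifying voxel get `NA` values.
#' @export
tract_weighted_stats <- function(maps, atlas, prob_floor = 0.5,
                                 weighted_sd = TRUE,
                                 subject_id = "subj", group = NA_character_) {
  dims <- dim(maps$fa)
  if (!all(dims == dim(atlas$prob)[1:3]))
    stopf("maps (%s) and atlas (%s) grids differ",
          paste(dims, collapse = "x"), paste(dim(atlas$prob)[1:3], collapse = "x"))
  pars <- map_parameters(maps)
  mapv <- lapply(maps[pars], as.vector)
  nt <- n_tracts(atlas)
  ncell <- nt * length(pars)
  tract_c <- par_c <- character(ncell)
  mu_c <- sd_c <- numeric(ncell)
  n_c <- integer(ncell)
  k <- 0L
  for (t in seq_len(nt)) {
    p <- as.vector(atlas$prob[, , , t])
    sel <- which(p >= prob_floor)
    wsel <- p[sel]
    for (par in pars) {
      k <- k + 1L
      tract_c[k] <- atlas$tract_names[t]
      par_c[k] <- par
      x <- mapv[[par]][sel]
      keep <- is.finite(x)
      x <- x[keep]; w <- wsel[keep]
      if (!length(x)) {
        mu_c[k] <- sd_c[k] <- NA_real_
        n_c[k] <- 0L
        next
      }
      mu_c[k] <- sum(w * x) / sum(w)
      sd_c[k] <- if (weighted_sd) sqrt(sum(w * (x - mu_c[k])^2) / sum(w))
                 else stats::sd(x)
      n_c[k] <- length(x)
    }
  }
  out <- tibble::tibble(
    subject_id = subject_id, group = group,
    tract = rep(tract_c, each = 2), parameter = rep(par_c, each = 2),
    feature = rep(c("mean", "sd"), ncell),
    value = as.vector(rbind(mu_c, sd_c)),
    n_voxels = rep(n_c, each = 2)
  )
  miss <- dplyr::filter(out, is.na(.data$value), .data$feature == "mean")
  if (nrow(miss))
    message(sprintf("tract_weighted_stats: no qualifying voxels in %d tract(s): %s",
                    nrow(miss), paste(unique(miss$tract), collapse = ", ")))
  out
}

#' Tract-volume quality control by coefficient of variation
#'
#' Tract volume (voxels with probability >= 0.5, times the voxel volume) is
#' computed per control subject; left/right tract volumes are averaged into
#' one merged tract. The coefficient of variation (SD / mean) across control
#' subjects flags unreliable segmentations: tracts with CoV above `threshold`
#' (default 0.25, far above anatomical volume variation) are excluded from
#' further analysis.
#'
#' @param atlas_per_subject Named list of [tract_atlas()] objects, one per
#'   subject (names = subject ids).
#' @param design Data frame with columns `subject_id`, `group`; CoV uses the
#'   `"HC"` rows only (>= 3 required).
#' @param threshold CoV exclusion threshold.
#' @param voxel_size Isotropic voxel edge (mm) for volumes.
#' @return A tibble (class `tract_qc`): `tract` (merged name), `mean_volume`,
#'   `cov`, `excluded`, `reason`.
#' @export
tract_volume_cov <- function(atlas_per_subject, design, threshold = 0.25,
                             voxel_size = 2.0) {
  hc_ids <- design$subject_id[design$group == "HC"]
  hc_ids <- intersect(hc_ids, names(atlas_per_subject))
  if (length(hc_ids) < 3) stopf("need >= 3 HC subjects, got %d", length(hc_ids))
  vv <- voxel_size^3
  vols <- purrr::map_dfr(hc_ids, function(id) {
    atl <- atlas_per_subject[[id]]
    v <- apply(atl$prob >= 0.5, 4, sum) * vv
    merged_tracts(atl) |>
      dplyr::mutate(subject_id = id, volume = v)
  })
  out <- vols |>
    dplyr::summarise(volume = mean(.data$volume),
                     .by = c("subject_id", "merged")) |>
    dplyr::summarise(mean_volume = mean(.data$volume),
                     sd_volume = stats::sd(.data$volume),
                     any_zero = any(.data$volume == 0),
                     .by = "merged") |>
    dplyr::mutate(
      cov = ifelse(.data$mean_volume > 0 & !.data$any_zero,
                   .data$sd_volume / .data$mean_volume, NA_real_),
      excluded = is.na(.data$cov) | .data$cov > threshold,
      reason = dplyr::case_when(
        is.na(cov) ~ "zero volume in a control subject",
        cov > threshold ~ sprintf("CoV %.3f > %.2f", cov, threshold),
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::rename(tract = "merged") |>
    dplyr::select("tract", "mean_volume", "cov", "excluded", "reason")
  class(out) <- c("tract_qc", class(out))
  out
}

#' Merge left/right tract statistics
#'
#' Paired tracts are replaced by the arithmetic mean of their left and right
#' values per subject, parameter and feature; midline tracts pass through.
#' With a full 72-tract atlas (31 pairs + 10 midline) this yields 41 merged
#' tracts. If one side is missing its partner's value is used alone (logged).
#'
#' @param table A tract feature tibble from [tract_weighted_stats()].
#' @param atlas The [tract_atlas()] supplying the laterality mapping.
#' @return A tibble with the same columns, `tract` now the merged name.
#' @export
merge_lr <- function(table, atlas) {
  mt <- merged_tracts(atlas)
  joined <- dplyr::inner_join(table, mt, by = "tract")
  n_side <- joined |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::distinct(.data$merged, .data$tract)
  expected <- mt |> dplyr::summarise(n_exp = dplyr::n(), .by = "merged")
  got <- n_side |> dplyr::summarise(n_got = dplyr::n(), .by = "merged")
  short <- dplyr::left_join(expected, got, by = "merged") |>
    dplyr::filter(.data$n_exp == 2, is.na(.data$n_got) | .data$n_got < 2)
  if (nrow(short))
    message(sprintf("merge_lr: using single available side for: %s",
                    paste(short$merged, collapse = ", ")))
  grp_cols <- intersect(c("subject_id", "group", "parameter", "feature"),
                        names(joined))
  joined |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     n_voxels = sum(.data$n_voxels),
                     .by = dplyr::all_of(c(grp_cols, "merged"))) |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value)) |>
    dplyr::rename(tract = "merged") |>
    dplyr::relocate(dplyr::all_of(grp_cols), "tract")
}
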