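#' Study configuration
#'
#' Bundles every knob of a factorial benchmark run: which acquisition
#' protocols, which processing pipelines, which smoothing kernels, the
#' synthetic cohort design, the artifact model and the statistical
#' thresholds. Group sizes default to the study cohorts per protocol
#' (3T-DTI 20 HC / 63 SLE, 3T-DKI 20/56, 7T-DTI 21/54).
#'
#' @param protocols Protocol names (see [protocol_scheme()]).
#' @param pipelines List of [pipeline_config()]s, or character step strings
#'   ("none", "MPPCA+Eddy", ...); defaults to all 8.
#' @param smoothing_sigmas Gaussian SDs in voxels (the standard sweep is
#'   0 to 1 in steps of 0.1).
#' @param seed Master seed; all randomness in the run derives from it.
#' @param group_sizes Named list protocol -> c(n_hc, n_sle); `NULL` for the
#'   study defaults.
#' @param grid_shape,n_tracts,tract_radius Synthetic atlas geometry.
#' @param affected_tracts,parameter,designed_d Group-effect design (tract
#'   names default to the first three tracts).
#' @param artifacts An [artifact_spec()].
#' @param mask_prob Probability floor for tract statistics (voxels below it
#'   are excluded).
#' @param cov_max Tract-volume CoV exclusion threshold.
#' @param alpha Significance level.
#' @param n_tracts_for_bonferroni Test count for the Bonferroni level.
#' @param threshold_reps Monte-Carlo replicates for null thresholds.
#' @return A `study_config` list.
#' @export
study_config <- function(protocols = c("3T-DTI", "3T-DKI", "7T-DTI"),
                         pipelines = NULL,
                         smoothing_sigmas = seq(0, 1, by = 0.1),
                         seed = 1L,
                         group_sizes = NULL,
                         grid_shape = 24, n_tracts = 12, tract_radius = 1.6,
                         affected_tracts = NULL, parameter = "fa",
                         designed_d = 0.8,
                         artifacts = artifact_spec(),
                         mask_prob = 0.5, cov_max = 0.25, alpha = 0.05,
                         n_tracts_for_bonferroni = 72,
                         threshold_reps = 2e5) {
  if (mask_prob <= 0 || mask_prob >= 1) stopf("mask_prob must be in (0, 1)")
  if (cov_max <= 0) stopf("cov_max must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  defaults <- list("3T-DTI" = c(20L, 63L), "3T-DKI" = c(20L, 56L),
                   "7T-DTI" = c(21L, 54L))
  if (is.null(group_sizes)) group_sizes <- defaults[protocols]
  if (is.null(pipelines)) pipelines <- enumerate_pipelines()
  pipelines <- lapply(pipelines, function(p) {
    if (is.character(p)) {
      steps <- if (identical(p, "none")) character(0) else strsplit(p, "+", fixed = TRUE)[[1]]
      pipeline_config(steps)
    } else p
  })
  if (is.list(artifacts) && !inherits(artifacts, "artifact_spec"))
    artifacts <- do.call(artifact_spec, artifacts)
  structure(
    list(protocols = protocols, pipelines = pipelines,
         smoothing_sigmas = smoothing_sigmas, seed = as.integer(seed),
         group_sizes = group_sizes, grid_shape = grid_shape,
         n_tracts = n_tracts, tract_radius = tract_radius,
         affected_tracts = affected_tracts, parameter = parameter,
         designed_d = designed_d, artifacts = artifacts,
         mask_prob = mask_prob, cov_max = cov_max, alpha = alpha,
         n_tracts_for_bonferroni = n_tracts_for_bonferroni,
         threshold_reps = threshold_reps),
    class = "study_config"
  )
}

#' Run the full factorial benchmark
#'
#' For each protocol a synthetic cohort is simulated once (all pipelines see
#' the same subjects and noise realizations, so pipeline contrasts are
#' paired); each subject is processed by every pipeline (shared step-prefix
#' results are cached), smoothed at every sigma, fitted (DKI on multi-shell
#' schemes, DTI otherwise), summarized into probability-weighted tract
#' statistics, and merged left/right. Effect sizes per (protocol, pipeline,
#' sigma) cell are then computed with per-protocol Monte-Carlo null
#' thresholds. Failures isolate their cell; the rest of the grid completes.
#'
#' @param config A [study_config()].
#' @param progress Print per-protocol progress messages.
#' @return A `study_result`: `comparisons` (tibble of d per protocol /
#'   pipeline / sigma / tract / parameter / feature with significance flags),
#'   `thresholds`, `qc`, `failed` (tibble of failed cells), `manifest`.
#' @export
run_study <- function(config, progress = FALSE) {
  t0 <- Sys.time()
  atlas <- build_atlas(config$grid_shape, config$n_tracts,
                       seed = derive_seed(config$seed, 1L),
                       radius = config$tract_radius)
  merged_names <- unique(merged_tracts(atlas)$merged)
  affected <- config$affected_tracts %||%
    merged_names[seq_len(min(3L, length(merged_names)))]
  fit_mask <- apply(atlas$prob, 1:3, max) >= config$mask_prob * 0.9

  all_rows <- list()
  failed <- list()
  for (pi in seq_along(config$protocols)) {
    prot <- config$protocols[pi]
    scheme <- protocol_scheme(prot)
    gs <- config$group_sizes[[prot]] %||% config$group_sizes[[pi]]
    pop <- population_spec(n_hc = gs[1], n_sle = gs[2],
                           affected_tracts = affected,
                           parameter = config$parameter,
                           direction = if (config$parameter == "fa") -1 else 1,
                           designed_d = config$designed_d)
    model <- if (scheme_dki_capable(scheme)) "DKI" else "DTI"
    design <- tibble::tibble(
      subject_id = c(sprintf("HC%03d", seq_len(pop$n_hc)),
                     sprintf("SLE%03d", seq_len(pop$n_sle))),
      group = c(rep("HC", pop$n_hc), rep("SLE", pop$n_sle))
    )
    if (progress)
      message(sprintf("[%s] %d subjects, model %s", prot, nrow(design), model))
    for (si in seq_len(nrow(design))) {
      sid <- design$subject_id[si]
      sseed <- derive_seed(config$seed, 1000L * pi + si)
      sim <- simulate_subject(pop, atlas, scheme, config$artifacts,
                              design$group[si], sseed, subject_id = sid)
      cache <- list(none = sim$data)
      chain_get <- function(steps) {
        key <- if (length(steps)) paste(steps, collapse = "+") else "none"
        if (!is.null(cache[[key]])) return(cache[[key]])
        prev <- chain_get(steps[-length(steps)])
        res <- switch(steps[length(steps)],
                      MPPCA = mppca_denoise(prev)$data,
                      Gibbs = gibbs_unring(prev),
                      Eddy = correct_motion_eddy(prev)$data)
        cache[[key]] <<- res
        res
      }
      for (pl in config$pipelines) {
        for (sg in config$smoothing_sigmas) {
          rows <- tryCatch({
            proc <- chain_get(pl$steps)
            if (sg > 0) proc <- smooth_gaussian(proc, sg)
            fit <- fit_wlls(proc, model, mask = fit_mask)
            maps <- suppressMessages(scalar_metrics(fit))
            st <- suppressMessages(
              tract_weighted_stats(maps, atlas, prob_floor = config$mask_prob,
                                   subject_id = sid, group = design$group[si]))
            merge_lr(st, atlas) |>
              dplyr::mutate(protocol = prot, pipeline = pl$name, sigma = sg)
          }, error = function(e) e)
          if (inherits(rows, "error")) {
            failed[[length(failed) + 1]] <- tibble::tibble(
              protocol = prot, pipeline = pl$name, sigma = sg,
              subject_id = sid, reason = conditionMessage(rows))
          } else {
            all_rows[[length(all_rows) + 1]] <- rows
          }
        }
      }
    }
  }
  feats <- dplyr::bind_rows(all_rows)
  failed <- dplyr::bind_rows(failed)

  comparisons <- list()
  thresholds <- list()
  qc <- list()
  for (prot in unique(feats$protocol)) {
    sub <- dplyr::filter(feats, .data$protocol == prot)
    for (pl in unique(sub$pipeline)) for (sg in unique(sub$sigma)) {
      cell <- dplyr::filter(sub, .data$pipeline == pl, .data$sigma == sg)
      cmp <- tryCatch(
        group_compare(cell, alpha = config$alpha,
                      n_tests = config$n_tracts_for_bonferroni,
                      reps = config$threshold_reps,
                      seed = derive_seed(config$seed, 77L)),
        error = function(e) e)
      if (inherits(cmp, "error")) {
        failed <- dplyr::bind_rows(failed, tibble::tibble(
          protocol = prot, pipeline = pl, sigma = sg, subject_id = NA,
          reason = conditionMessage(cmp)))
        next
      }
      comparisons[[length(comparisons) + 1]] <-
        dplyr::mutate(tidy(cmp), protocol = prot, pipeline = pl, sigma = sg,
                      .before = 1)
      thresholds[[length(thresholds) + 1]] <- tibble::tibble(
        protocol = prot, pipeline = pl, sigma = sg,
        threshold_unc = attr(cmp, "threshold_unc"),
        threshold_bonf = attr(cmp, "threshold_bonf"))
    }
  }
  structure(
    list(comparisons = dplyr::bind_rows(comparisons),
         thresholds = dplyr::bind_rows(thresholds) |> dplyr::distinct(),
         features = feats,
         failed = failed,
         atlas = atlas,
         manifest = list(seed = config$seed,
                         config_hash = rlang::hash(config),
                         affected_tracts = affected,
                         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d comparison cells (%d failed); seed %d; %.1f s>\n",
              nrow(dplyr::distinct(x$comparisons,
                                   .data$protocol, .data$pipeline, .data$sigma)),
              nrow(x$failed), x$manifest$seed, x$manifest$elapsed_s))
  invisible(x)
}

#' Classify smoothing-sweep response patterns
#'
#' Per protocol, parameter and feature, averages d over tracts at each sigma
#' and classifies the curve into the four canonical responses: monotone
#' `"decline"`, `"little influence"` (flat within `flat_tol`),
#' `"rise-then-decline"` (interior peak; its sigma reported), or
#' `"slight rise"`.
#'
#' @param result A `study_result` (needs >= 3 sigma levels) or a tibble like
#'   its `comparisons` field.
#' @param feature Feature to aggregate (default `"mean"`).
#' @param flat_tol Absolute d range treated as flat.
#' @return Tibble: grouping columns, `pattern`, `peak_sigma`, `d_range`.
#' @export
smoothing_sweep_report <- function(result, feature = "mean", flat_tol = 0.01) {
  comp <- if (inherits(result, "study_result")) result$comparisons else result
  grp <- intersect(c("protocol", "pipeline", "parameter"), names(comp))
  curves <- comp |>
    dplyr::filter(.data$feature == .env$feature, !is.na(.data$d)) |>
    dplyr::summarise(dbar = mean(.data$d), .by = dplyr::all_of(c(grp, "sigma"))) |>
    dplyr::arrange(.data$sigma)
  if (dplyr::n_distinct(curves$sigma) < 3)
    stopf("need >= 3 sigma levels, got %d", dplyr::n_distinct(curves$sigma))
  curves |>
    dplyr::summarise(pattern = classify_curve(.data$sigma, .data$dbar, flat_tol),
                     peak_sigma = .data$sigma[which.max(.data$dbar)],
                     d_range = max(.data$dbar) - min(.data$dbar),
                     .by = dplyr::all_of(grp)) |>
    dplyr::mutate(peak_sigma = ifelse(.data$pattern == "rise-then-decline",
                                      .data$peak_sigma, NA_real_))
}

classify_curve <- function(sigma, dbar, flat_tol) {
  o <- order(sigma)
  y <- dbar[o]
  if (max(y) - min(y) < flat_tol) return("little influence")
  imax <- which.max(y)
  n <- length(y)
  if (imax == 1) return("decline")
  if (imax == n) return("slight rise")
  if (y[imax] - y[1] < flat_tol) "decline" else "rise-then-decline"
}
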