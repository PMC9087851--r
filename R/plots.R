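#' Plot per-tract effect sizes by protocol and parameter
#'
#' Box plots of Cohen's d across tracts, faceted by parameter, coloured by
#' protocol, with the significance threshold drawn as a dotted line.
#'
#' @param comparisons `study_result$comparisons` or a bound set of tidy
#'   comparisons with columns `protocol`, `parameter`, `feature`, `d`.
#' @param feature Feature to plot.
#' @param threshold Optional |d| significance line.
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(comparisons, feature = "mean", threshold = NULL) {
  df <- dplyr::filter(tibble::as_tibble(comparisons),
                      .data$feature == .env$feature, !is.na(.data$d))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$protocol, y = .data$d,
                                        fill = .data$protocol)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, alpha = 0.8) +
    ggplot2::geom_jitter(width = 0.15, size = 0.5, alpha = 0.5) +
    ggplot2::facet_wrap(~ toupper(parameter)) +
    ggplot2::labs(x = NULL, y = "Cohen's d (across tracts)",
                  title = sprintf("Effect sizes (%s of parameter)", feature)) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dotted",
                                 colour = "darkorange")
  p
}

#' Plot per-step impact on effect sizes
#'
#' @param impact Output of [step_impact()].
#' @return A ggplot object.
#' @export
plot_step_impact <- function(impact) {
  has_prot <- "protocol" %in% names(impact)
  p <- ggplot2::ggplot(impact, ggplot2::aes(x = .data$step, y = .data$delta_d,
                                            fill = .data$step)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "processing step",
                  y = expression(Delta * " d (with - without)"),
                  title = "Impact of each processing step on effect size") +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
  if (has_prot && "parameter" %in% names(impact)) {
    p <- p + ggplot2::facet_grid(toupper(parameter) ~ protocol)
  } else if ("parameter" %in% names(impact)) {
    p <- p + ggplot2::facet_wrap(~ toupper(parameter))
  }
  p
}

#' Plot the smoothing sweep
#'
#' Tract-averaged d against smoothing sigma, one line per parameter,
#' faceted by protocol.
#'
#' @param comparisons `study_result$comparisons` (several sigma levels).
#' @param feature Feature to aggregate.
#' @return A ggplot object.
#' @export
plot_smoothing_sweep <- function(comparisons, feature = "mean") {
  grp <- intersect(c("protocol", "parameter"), names(comparisons))
  df <- tibble::as_tibble(comparisons) |>
    dplyr::filter(.data$feature == .env$feature, !is.na(.data$d)) |>
    dplyr::summarise(dbar = mean(.data$d), .by = dplyr::all_of(c(grp, "sigma")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$dbar,
                                        colour = toupper(.data$parameter))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression("smoothing " * sigma * " (voxels)"),
                  y = "tract-averaged Cohen's d", colour = "parameter",
                  title = "Effect size vs. Gaussian smoothing") +
    ggplot2::theme_bw()
  if ("protocol" %in% grp) p <- p + ggplot2::facet_wrap(~ protocol)
  p
}

#' Plot the tract-volume QC report
#'
#' CoV per merged tract with the exclusion threshold line.
#'
#' @param qc A `tract_qc` tibble from [tract_volume_cov()].
#' @param threshold Exclusion threshold to draw.
#' @return A ggplot object.
#' @export
plot_tract_qc <- function(qc, threshold = 0.25) {
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$cov,
                                   y = stats::reorder(.data$tract, .data$cov),
                                   fill = .data$excluded)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "coefficient of variation of tract volume (HC)",
                  y = NULL, fill = "excluded") +
    ggplot2::theme_bw()
}
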