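#' Cohen's d with pooled standard deviation
#'
#' \deqn{d = (\bar u_{HC} - \bar u_{SLE}) / s,\quad
#'   s = \sqrt{\frac{(n_{HC}-1)s^2_{HC} + (n_{SLE}-1)s^2_{SLE}}
#'                  {n_{HC}+n_{SLE}-2}}}
#' For an unbalanced design the pooled SD mostly reflects the larger group.
#' A zero pooled SD yields `NA` (logged).
#'
#' @param values_hc,values_sle Per-subject values for the two groups
#'   (each length >= 2).
#' @return Cohen's d (positive when the control mean is larger).
#' @export
cohens_d <- function(values_hc, values_sle) {
  values_hc <- values_hc[is.finite(values_hc)]
  values_sle <- values_sle[is.finite(values_sle)]
  n1 <- length(values_hc); n2 <- length(values_sle)
  if (n1 < 2 || n2 < 2) stopf("both groups need >= 2 finite values (got %d, %d)", n1, n2)
  s <- sqrt(((n1 - 1) * stats::var(values_hc) + (n2 - 1) * stats::var(values_sle)) /
              (n1 + n2 - 2))
  if (s == 0) {
    message("cohens_d: zero pooled SD, returning NA")
    return(NA_real_)
  }
  (mean(values_hc) - mean(values_sle)) / s
}

#' Sign adjustment of effect sizes per parameter
#'
#' Pathology typically lowers FA but raises the diffusivities, so d for MD,
#' RD and AD is negated to make all parameters' expected effects positive and
#' comparable. The flip set is configurable (kurtosis parameters are not
#' flipped by default).
#'
#' @param d Effect size(s).
#' @param parameter Parameter label(s) (case-insensitive; recycled).
#' @param flip Parameters whose d is negated.
#' @param known All recognized parameter labels.
#' @return Adjusted effect size(s).
#' @export
sign_adjust <- function(d, parameter, flip = c("md", "rd", "ad"),
                        known = c("fa", "md", "ad", "rd", "mk", "ak", "rk")) {
  parameter <- tolower(parameter)
  bad <- setdiff(unique(parameter), tolower(known))
  if (length(bad)) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  ifelse(parameter %in% tolower(flip), -d, d)
}

#' Null significance threshold for |Cohen's d|
#'
#' The two-sided threshold at level `alpha` under no true effect: the edge
#' of the central `1 - alpha` interval of the null sampling distribution of
#' d. Method `"mc"` (default) simulates two same-distribution normal groups
#' `reps` times, computes d with the pooled-SD formula, and returns the
#' `1 - alpha/2` quantile of the (symmetric) signed d distribution —
#' equivalently the `1 - alpha` quantile of |d|. Method `"central_t"` is the
#' deterministic closed form `qt(1 - alpha/2, n1 + n2 - 2) * sqrt(1/n1 +
#' 1/n2)` (under normality d is exactly a scaled central t); the two methods
#' agree within Monte-Carlo error.
#'
#' @param n_hc,n_sle Group sizes.
#' @param alpha Two-sided significance level.
#' @param method `"mc"` or `"central_t"`.
#' @param reps Monte-Carlo replicates (>= 1e5 recommended).
#' @param seed Seed for the Monte-Carlo draw.
#' @return The |d| threshold.
#' @export
null_threshold <- function(n_hc, n_sle, alpha = 0.05,
                           method = c("mc", "central_t"),
                           reps = 2e5, seed = 1L) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (method == "central_t") {
    return(stats::qt(1 - alpha / 2, n_hc + n_sle - 2) * sqrt(1 / n_hc + 1 / n_sle))
  }
  withr::local_seed(seed)
  d <- null_d_samples(n_hc, n_sle, reps)
  unname(stats::quantile(abs(d), 1 - alpha, type = 7))
}

# Vectorized null Cohen's d draws: both groups standard normal.
null_d_samples <- function(n1, n2, reps) {
  reps <- as.integer(reps)
  x1 <- matrix(stats::rnorm(n1 * reps), n1, reps)
  x2 <- matrix(stats::rnorm(n2 * reps), n2, reps)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  s <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  (m1 - m2) / s
}

#' Per-test confidence level after Bonferroni correction
#'
#' `1 - alpha / n_tests`; correcting 72 tract tests at alpha = 0.05 gives the
#' 99.9% confidence level. Feed the complement (as alpha) to
#' [null_threshold()] for the corrected d threshold.
#'
#' @param alpha Family-wise significance level.
#' @param n_tests Number of tests (>= 1).
#' @return The per-test confidence level.
#' @export
bonferroni_level <- function(alpha = 0.05, n_tests = 72) {
  if (n_tests < 1) stopf("n_tests must be >= 1")
  1 - alpha / n_tests
}

#' Family-wise false-positive bound via the exact binomial tail
#'
#' Probability of observing more than `k` significant tracts out of
#' `n_tracts` independent tests when no true effect exists anywhere:
#' `P(X > k)`, `X ~ Binomial(n_tracts, alpha)`, by exact summation. With 72
#' tracts at the uncorrected 5% level, more than seven significant tracts
#' occurs with probability below 5%, so such an observation indicates a true
#' effect in at least some tracts.
#'
#' @param n_tracts Number of tracts tested.
#' @param alpha Per-test significance level.
#' @param k Count threshold (strictly exceeded).
#' @return `P(X > k)`.
#' @export
familywise_binomial <- function(n_tracts = 72, alpha = 0.05, k = 7) {
  if (k >= n_tracts) return(0)
  if (k < 0) return(1)
  sum(stats::dbinom((k + 1):n_tracts, n_tracts, alpha))
}

#' Group comparison: per-tract, per-feature effect sizes
#'
#' Computes sign-adjusted Cohen's d for every tract x parameter x feature cell
#' of a tract feature table, flags significance against the protocol's
#' uncorrected Monte-Carlo null threshold and the Bonferroni-corrected one,
#' and returns a `group_comparison` object.
#'
#' @param table Tract feature tibble ([tract_weighted_stats()] /
#'   [merge_lr()] output) with columns `subject_id`, `group`, `tract`,
#'   `parameter`, `feature`, `value`.
#' @param alpha Significance level.
#' @param n_tests Number of tests assumed for the Bonferroni threshold.
#' @param threshold_method,reps,seed Passed to [null_threshold()].
#' @param excluded_tracts Tract names (merged) to drop before comparison
#'   (e.g. from [tract_volume_cov()]).
#' @return A `group_comparison`: tibble with `tract`, `parameter`, `feature`,
#'   `d`, `significant_unc`, `significant_bonf`, plus attributes
#'   `threshold_unc`, `threshold_bonf`, `n_hc`, `n_sle`.
#' @export
group_compare <- function(table, alpha = 0.05, n_tests = 72,
                          threshold_method = "mc", reps = 2e5, seed = 1L,
                          excluded_tracts = character()) {
  table <- dplyr::filter(table, !.data$tract %in% excluded_tracts)
  ns <- table |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::count(.data$group)
  n_hc <- ns$n[ns$group == "HC"]
  n_sle <- ns$n[ns$group == "SLE"]
  if (!length(n_hc) || !length(n_sle)) stopf("need both HC and SLE subjects")
  thr_unc <- null_threshold(n_hc, n_sle, alpha, threshold_method, reps, seed)
  thr_bonf <- null_threshold(n_hc, n_sle, 1 - bonferroni_level(alpha, n_tests),
                             threshold_method, reps, seed)
  out <- table |>
    dplyr::summarise(
      d = tryCatch(cohens_d(.data$value[.data$group == "HC"],
                            .data$value[.data$group == "SLE"]),
                   error = function(e) NA_real_),
      .by = c("tract", "parameter", "feature")
    ) |>
    dplyr::mutate(
      d = sign_adjust(.data$d, .data$parameter),
      significant_unc = !is.na(.data$d) & .data$d > thr_unc,
      significant_bonf = !is.na(.data$d) & .data$d > thr_bonf
    )
  structure(out, class = c("group_comparison", class(out)),
            threshold_unc = thr_unc, threshold_bonf = thr_bonf,
            n_hc = n_hc, n_sle = n_sle, alpha = alpha)
}

#' Fraction of tracts with a significant effect
#'
#' @param comparison A `group_comparison` (or plain tibble with `d`).
#' @param threshold Significance threshold for d (> 0); defaults to the
#'   comparison's uncorrected threshold.
#' @return Tibble: `parameter`, `feature`, `n_tracts`, `n_significant`,
#'   `fraction`.
#' @export
significant_fraction <- function(comparison, threshold = NULL) {
  threshold <- threshold %||% attr(comparison, "threshold_unc")
  if (is.null(threshold) || threshold <= 0) stopf("threshold must be > 0")
  tibble::as_tibble(comparison) |>
    dplyr::filter(!is.na(.data$d)) |>
    dplyr::summarise(
      n_tracts = dplyr::n(),
      n_significant = sum(.data$d > threshold),
      fraction = .data$n_significant / .data$n_tracts,
      .by = c("parameter", "feature")
    )
}

#' Per-step impact on effect sizes
#'
#' The impact of one processing step is the mean, over the 4 matched pipeline
#' pairs (P with the step vs P without it), of the difference in
#' tract-averaged d. Requires all 8 pipeline results. Reported per parameter
#' (and per whatever grouping columns are present, e.g. protocol), with grand
#' means available via [step_impact_grand()].
#'
#' @param comparisons Tibble binding the `group_comparison` rows of all 8
#'   pipelines, with a `pipeline` column naming each (as in
#'   [enumerate_pipelines()]) plus optionally `protocol`.
#' @param steps Steps to evaluate.
#' @param feature Which feature's d to aggregate (default `"mean"`).
#' @return Tibble: grouping columns, `step`, `delta_d`.
#' @export
step_impact <- function(comparisons, steps = c("MPPCA", "Gibbs", "Eddy"),
                        feature = "mean") {
  all_names <- vapply(enumerate_pipelines(), function(p) p$name, "")
  grp <- intersect(c("protocol", "parameter"), names(comparisons))
  have <- unique(comparisons$pipeline)
  missing_p <- setdiff(all_names, have)
  if (length(missing_p))
    stopf("missing pipeline results: %s", paste(missing_p, collapse = ", "))
  davg <- comparisons |>
    dplyr::filter(.data$feature == .env$feature, !is.na(.data$d)) |>
    dplyr::summarise(dbar = mean(.data$d), .by = dplyr::all_of(c(grp, "pipeline")))
  purrr::map_dfr(steps, function(s) {
    pairs <- purrr::map_dfr(enumerate_pipelines(), function(p) {
      if (s %in% p$steps) return(NULL)
      with_s <- pipeline_config(c(p$steps, s))$name
      tibble::tibble(without = p$name, with = with_s)
    })
    dplyr::inner_join(
      dplyr::inner_join(pairs, davg, by = c(without = "pipeline")),
      davg, by = c(grp, c(with = "pipeline")),
      suffix = c("_without", "_with")
    ) |>
      dplyr::summarise(delta_d = mean(.data$dbar_with - .data$dbar_without),
                       .by = dplyr::all_of(grp)) |>
      dplyr::mutate(step = s, .before = 1)
  })
}

#' Grand-mean step impact across parameters and protocols
#'
#' @param impact Output of [step_impact()].
#' @return Tibble: `step`, `delta_d` (grand mean).
#' @export
step_impact_grand <- function(impact) {
  dplyr::summarise(impact, delta_d = mean(.data$delta_d), .by = "step")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %d cells; HC %d vs SLE %d; |d| thresholds %.3f (unc) / %.3f (bonf)>\n",
              nrow(x), attr(x, "n_hc"), attr(x, "n_sle"),
              attr(x, "threshold_unc"), attr(x, "threshold_bonf")))
  NextMethod()
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The comparison as a plain tibble.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble with group sizes, thresholds and significant-tract counts.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_hc = attr(x, "n_hc"), n_sle = attr(x, "n_sle"),
    threshold_unc = attr(x, "threshold_unc"),
    threshold_bonf = attr(x, "threshold_bonf"),
    n_cells = nrow(x),
    n_significant_unc = sum(x$significant_unc, na.rm = TRUE),
    n_significant_bonf = sum(x$significant_bonf, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
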