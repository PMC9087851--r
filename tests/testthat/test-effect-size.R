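test_that("Cohen's d matches the pooled-SD hand example and symmetries", {
  expect_equal(cohens_d(c(0.5, 0.6, 0.7), c(0.4, 0.5, 0.6)), 1)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 4), c(2, 5, 6)),
               -cohens_d(c(2, 5, 6), c(1, 2, 4)))
  # affine rescaling of both groups leaves d unchanged
  a <- rnorm(10); b <- rnorm(12, 0.5)
  expect_equal(cohens_d(3 * a + 7, 3 * b + 7), cohens_d(a, b), tolerance = 1e-12)
  # zero pooled SD -> NA with a log message
  expect_message(dz <- cohens_d(c(1, 1, 1), c(1, 1, 1)), "zero pooled SD")
  expect_true(is.na(dz))
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("inflating only the larger group's SD lowers |d|", {
  set.seed(10)
  big <- rnorm(56, 0, 1); small <- rnorm(20, 1, 1)
  d1 <- abs(cohens_d(small, big))
  d2 <- abs(cohens_d(small, big * 3))
  expect_lt(d2, d1)
})

test_that("sign adjustment flips exactly the diffusivity parameters", {
  expect_equal(sign_adjust(-0.4, "MD"), 0.4)
  expect_equal(sign_adjust(0.7, "FA"), 0.7)
  expect_equal(sign_adjust(sign_adjust(-0.4, "rd"), "rd"), -0.4)  # involution
  expect_equal(sign_adjust(c(0.2, -0.3), c("fa", "ad")), c(0.2, 0.3))
  expect_error(sign_adjust(1, "bogus"), "unknown")
})

test_that("null thresholds: closed form, Monte-Carlo agreement, and limits", {
  ct <- null_threshold(56, 20, method = "central_t")
  expect_equal(ct, qt(0.975, 74) * sqrt(1 / 56 + 1 / 20), tolerance = 1e-12)
  expect_equal(ct, 0.519, tolerance = 1e-3)
  mc <- null_threshold(56, 20, method = "mc", reps = 2e5, seed = 1)
  expect_lt(abs(mc - ct), 0.01)
  # alpha -> 1 drives the threshold to 0
  expect_lt(null_threshold(56, 20, alpha = 0.999, method = "central_t"), 0.01)
  expect_error(null_threshold(10, 10, alpha = 1.5), "alpha")
})

test_that("Bonferroni level and the family-wise binomial bound are exact", {
  expect_equal(bonferroni_level(0.05, 72), 1 - 0.05 / 72)
  expect_equal(round(100 * bonferroni_level(0.05, 72), 1), 99.9)
  expect_equal(bonferroni_level(0.05, 1), 0.95)
  # corrected threshold exceeds uncorrected
  expect_gt(null_threshold(56, 20, alpha = 1 - bonferroni_level(0.05, 72),
                           method = "central_t"),
            null_threshold(56, 20, method = "central_t"))
  expect_equal(familywise_binomial(72, 0.05, 7),
               1 - pbinom(7, 72, 0.05), tolerance = 1e-12)
  expect_lt(familywise_binomial(72, 0.05, 7), 0.05)
  expect_equal(familywise_binomial(72, 0.05, 72), 0)
  expect_equal(familywise_binomial(72, 0.05, -1), 1)
})

test_that("group comparison flags significance against both thresholds", {
  set.seed(11)
  tracts <- sprintf("t%02d", 1:6)
  subj <- c(sprintf("h%02d", 1:15), sprintf("p%02d", 1:15))
  grp <- rep(c("HC", "SLE"), each = 15)
  tab <- tidyr::crossing(tibble::tibble(subject_id = subj, group = grp),
                         tract = tracts, parameter = "fa", feature = "mean") |>
    dplyr::mutate(value = rnorm(dplyr::n(), 0.5, 0.02) +
                    ifelse(group == "SLE" & tract %in% tracts[1:2], -0.08, 0))
  cmp <- group_compare(tab, threshold_method = "central_t")
  td <- tidy(cmp)
  expect_true(all(td$significant_unc[td$tract %in% tracts[1:2]]))
  gl <- glance(cmp)
  expect_equal(gl$n_hc, 15)
  expect_gt(attr(cmp, "threshold_bonf"), attr(cmp, "threshold_unc"))
  fr <- significant_fraction(cmp)
  expect_equal(fr$n_tracts, 6)
  expect_gte(fr$fraction, 2 / 6)
  # 31 of 41 is the printed 76%
  expect_equal(round(31 / 41, 2), 0.76)
})

test_that("step impact isolates the step that moved the effect sizes", {
  pls <- vapply(enumerate_pipelines(), function(p) p$name, "")
  base <- tidyr::crossing(pipeline = pls, tract = sprintf("t%d", 1:5),
                          parameter = "fa", feature = "mean") |>
    dplyr::mutate(d = 0.5 + ifelse(grepl("Eddy", pipeline), 0.1, 0))
  imp <- step_impact(base)
  expect_equal(imp$delta_d[imp$step == "Eddy"], 0.1, tolerance = 1e-12)
  expect_equal(imp$delta_d[imp$step == "MPPCA"], 0, tolerance = 1e-12)
  expect_equal(imp$delta_d[imp$step == "Gibbs"], 0, tolerance = 1e-12)
  # identical pipelines -> all zero
  flat <- dplyr::mutate(base, d = 0.4)
  expect_true(all(abs(step_impact(flat)$delta_d) < 1e-12))
  # missing pipeline is an error naming it
  expect_error(step_impact(dplyr::filter(base, pipeline != "Gibbs+Eddy")),
               "Gibbs\\+Eddy")
  expect_equal(step_impact_grand(imp)$delta_d[imp$step == "Eddy"], 0.1)
})
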