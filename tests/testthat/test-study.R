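test_that("a minimal study runs end to end and is seed-deterministic", {
  cfg <- study_config(protocols = "7T-DTI", pipelines = list("none"),
                      smoothing_sigmas = 0, seed = 4,
                      group_sizes = list("7T-DTI" = c(3L, 3L)),
                      grid_shape = 16, n_tracts = 4, designed_d = 1.2,
                      artifacts = artifact_spec(snr_b0 = 60),
                      threshold_reps = 2e4)
  r1 <- run_study(cfg)
  expect_equal(nrow(r1$failed), 0)
  expect_equal(unique(r1$comparisons$pipeline), "none")
  expect_equal(unique(r1$comparisons$sigma), 0)
  # per-protocol comparison cells: tracts x parameters x features
  expect_setequal(unique(r1$comparisons$parameter), c("fa", "md", "ad", "rd"))
  expect_setequal(unique(r1$comparisons$feature), c("mean", "sd"))
  r2 <- run_study(cfg)
  expect_identical(r1$comparisons$d, r2$comparisons$d)
  expect_equal(r1$manifest$seed, 4)
})

test_that("invalid study configurations are rejected", {
  expect_error(study_config(mask_prob = 1.2), "mask_prob")
  expect_error(study_config(alpha = 0), "alpha")
  expect_error(study_config(cov_max = -1), "cov_max")
})

test_that("sweep classification recognises the four canonical patterns", {
  mk <- function(par, dvals) {
    tidyr::crossing(sigma = seq(0, 1, by = 0.25), tract = c("a", "b")) |>
      dplyr::mutate(parameter = par, feature = "mean",
                    protocol = "P", pipeline = "none",
                    d = dvals[match(sigma, seq(0, 1, by = 0.25))])
  }
  comp <- dplyr::bind_rows(
    mk("fa", c(0.8, 0.7, 0.6, 0.5, 0.4)),       # monotone decline
    mk("md", c(0.500, 0.504, 0.501, 0.498, 0.503)), # flat
    mk("ak", c(0.5, 0.6, 0.7, 0.6, 0.4)),       # rise then decline
    mk("rd", c(0.4, 0.45, 0.5, 0.55, 0.6))      # slight rise
  )
  sw <- smoothing_sweep_report(comp)
  get <- function(p) sw$pattern[sw$parameter == p]
  expect_equal(get("fa"), "decline")
  expect_equal(get("md"), "little influence")
  expect_equal(get("ak"), "rise-then-decline")
  expect_equal(sw$peak_sigma[sw$parameter == "ak"], 0.5)
  expect_equal(get("rd"), "slight rise")
  expect_error(smoothing_sweep_report(dplyr::filter(comp, sigma < 0.3)), ">= 3")
})

test_that("plot builders return ggplot objects", {
  comp <- tidyr::crossing(protocol = c("A", "B"), parameter = c("fa", "md"),
                          feature = "mean", sigma = c(0, 0.5),
                          tract = c("t1", "t2")) |>
    dplyr::mutate(d = runif(dplyr::n()))
  expect_s3_class(plot_effect_sizes(comp), "ggplot")
  expect_s3_class(plot_smoothing_sweep(comp), "ggplot")
  imp <- tidyr::crossing(step = c("MPPCA", "Gibbs", "Eddy"),
                         parameter = "fa", protocol = "A") |>
    dplyr::mutate(delta_d = c(0.1, -0.05, 0))
  expect_s3_class(plot_step_impact(imp), "ggplot")
  qc <- tibble::tibble(tract = c("a", "b"), mean_volume = c(10, 20),
                       cov = c(0.1, 0.4), excluded = c(FALSE, TRUE),
                       reason = c(NA, "CoV"))
  expect_s3_class(plot_tract_qc(qc), "ggplot")
})
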