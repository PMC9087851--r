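test_that("pipeline enumeration covers the 2^3 subsets with balanced pairs", {
  pls <- enumerate_pipelines()
  expect_length(pls, 8)
  names_all <- vapply(pls, function(p) p$name, "")
  expect_true("none" %in% names_all)
  expect_true("Gibbs+Eddy" %in% names_all)
  expect_equal(anyDuplicated(names_all), 0)
  for (s in c("MPPCA", "Gibbs", "Eddy")) {
    expect_equal(sum(vapply(pls, function(p) s %in% p$steps, TRUE)), 4)
  }
  expect_error(pipeline_config("TopUp"), "unknown")
})

test_that("MPPCA leaves a noise-free low-rank series untouched", {
  set.seed(4)
  base <- array(runif(14^3), c(14, 14, 14))
  sig <- array(outer(as.vector(base), seq(1, 2, length.out = 12)),
               c(14, 14, 14, 12)) + 5
  dd <- dwi_dataset(sig, mini_scheme(10))
  res <- mppca_denoise(dd)
  expect_lt(max(abs(res$data$signal - sig)), 1e-6)
  expect_lt(max(res$sigma), 1e-6)
})

test_that("MPPCA estimates the noise level of a pure-noise field", {
  set.seed(5)
  sch <- mini_scheme(14, n_b0 = 2)
  arr <- array(rnorm(14^3 * 16, mean = 10), c(14, 14, 14, 16))
  res <- mppca_denoise(dwi_dataset(arr, sch))
  expect_equal(median(res$sigma), 1, tolerance = 0.08)
})

test_that("MPPCA reduces the error of a noisy phantom", {
  tis <- fix_tissue()
  sch <- mini_scheme(14, n_b0 = 2)
  clean <- forward_signal(tis, sch)
  noisy <- add_rician_noise(clean, artifact_spec(snr_b0 = 20), seed = 3)
  den <- mppca_denoise(noisy)
  mse <- function(x) mean((x$signal - clean$signal)^2)
  expect_lt(mse(den$data), mse(noisy))
  expect_error(mppca_denoise(dwi_dataset(array(1, c(6, 6, 6, 6)), mini_scheme(4))),
               ">= 10")
})

test_that("subvoxel-shift unringing removes truncation ripples, not structure", {
  box <- box_dataset()
  rung <- apply_gibbs(box, artifact_spec(gibbs_truncation = 0.6))
  un <- gibbs_unring(rung)
  mids <- 20:28
  tv_line <- function(x, j) total_variation(x[, j, 2, 1])
  tv0 <- mean(vapply(mids, function(j) tv_line(box$signal, j), 1))
  tvr <- mean(vapply(mids, function(j) tv_line(rung$signal, j), 1))
  tvu <- mean(vapply(mids, function(j) tv_line(un$signal, j), 1))
  # >= 30% of the truncation-induced TV excess removed
  expect_lt(tvu, tvr - 0.3 * (tvr - tv0))
  # a ring-free smooth image changes by < 0.5% RMS
  x <- outer(exp(-((1:48) - 24)^2 / 80), exp(-((1:48) - 20)^2 / 90))
  smooth_img <- dwi_dataset(array(rep(x, 3), c(48, 48, 3, 1)) + 1e-9,
                            acquisition_scheme(0, matrix(0, 1, 3), 2))
  us <- gibbs_unring(smooth_img)
  expect_lt(sqrt(mean((us$signal - smooth_img$signal)^2)) / max(x), 0.005)
  # the degenerate single-step search still runs and helps monotonically less
  un1 <- gibbs_unring(rung, max_shift_steps = 1)
  tvu1 <- mean(vapply(mids, function(j) tv_line(un1$signal, j), 1))
  expect_lte(tvu, tvu1 + 1e-9)
})

test_that("Gaussian smoothing has the documented kernel and conservation", {
  sch <- acquisition_scheme(0, matrix(0, 1, 3), 2)
  delta <- array(0, c(21, 21, 21, 1)); delta[11, 11, 11, 1] <- 1
  dd <- dwi_dataset(delta, sch)
  expect_identical(smooth_gaussian(dd, 0)$signal, delta)
  sm <- smooth_gaussian(dd, 1)
  expect_equal(sm$signal[11, 11, 11, 1], (2 * pi)^(-3 / 2), tolerance = 0.02)
  expect_equal(sum(sm$signal), 1, tolerance = 1e-6)      # reflecting boundaries
  set.seed(6)
  noise <- dwi_dataset(array(rnorm(18^3), c(18, 18, 18, 1)) + 10, sch)
  v <- vapply(c(0.3, 0.6, 1), function(s) var(as.vector(smooth_gaussian(noise, s)$signal)), 1)
  expect_true(all(diff(v) < 0))
  expect_error(smooth_gaussian(dd, -1), ">= 0")
})

test_that("self-registration of unperturbed data keeps every volume still", {
  tis <- fix_tissue()
  fw <- forward_signal(tis, mini_scheme(8))
  cor <- correct_motion_eddy(fw, model_iterations = 1, max_iter = 150)
  p <- as.matrix(cor$transforms[, c("rx", "ry", "rz", "tx", "ty", "tz")])
  expect_lt(max(abs(p[, 1:3])) * 180 / pi, 0.05)
  expect_lt(max(abs(p[, 4:6])), 0.05)
  expect_identical(cor$data$signal, fw$signal)
  # b-values never altered by any step
  expect_identical(cor$data$scheme$bvalues, fw$scheme$bvalues)
})

test_that("b-vectors rotate with the rigid part in closed form", {
  r <- tractsens:::rotation_matrix(c(0, 0, 3 * pi / 180))
  v <- rotate_bvecs(matrix(c(1, 0, 0), 1), r)
  expect_equal(as.numeric(v), c(cos(3 * pi / 180), sin(3 * pi / 180), 0),
               tolerance = 1e-12)
  # involution through the transpose
  expect_equal(rotate_bvecs(v, t(r)), matrix(c(1, 0, 0), 1), tolerance = 1e-12)
})

test_that("a simulator-translated volume is recovered by registration", {
  # needs a structurally informative phantom: registration accuracy degrades
  # below ~24^3 with few tracts (see the methods vignette)
  atlas <- build_atlas(24, 12, seed = 7)
  tis <- sample_subject(population_spec(n_hc = 2, n_sle = 2), atlas, "HC",
                        seed = 5)
  fw <- forward_signal(tis, mini_scheme(12))
  dims <- dim(fw$signal)[1:3]
  mt <- me_matrix(me_params(trans = c(1.5, 0, 0)), dims)
  sig <- fw$signal
  sig[, , , 5] <- tractsens:::resample_affine(fw$signal[, , , 5], mt)
  cor <- suppressWarnings(
    correct_motion_eddy(tractsens:::with_signal(fw, sig),
                        model_iterations = 1, max_iter = 200))
  res <- residual_transform(mt, cor$transforms$matrix[[5]], dims)
  expect_lt(res$disp, 0.25)
})
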