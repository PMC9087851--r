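test_that("design matrices have the documented shapes and b0 rows", {
  expect_equal(dim(design_matrix(protocol_scheme("3T-DTI"), "DTI")), c(72, 7))
  expect_equal(dim(design_matrix(protocol_scheme("3T-DKI"), "DKI")), c(65, 22))
  a <- design_matrix(protocol_scheme("3T-DKI"), "DKI")
  b0row <- which(scheme_b0(protocol_scheme("3T-DKI")))[1]
  expect_equal(a[b0row, ], c(1, rep(0, 21)))
  expect_error(design_matrix(protocol_scheme("3T-DTI"), "DKI"), "shells|22")
  tiny <- acquisition_scheme(c(0, rep(1000, 4)),
                             rbind(matrix(0, 1, 3), tractsens:::hemisphere_dirs(4)), 2)
  expect_error(design_matrix(tiny, "DTI"), "7")
})

test_that("noise-free forward signals are recovered to numerical precision", {
  tis <- fix_tissue()
  sch <- protocol_scheme("3T-DKI")
  fw <- forward_signal(tis, sch)
  fit <- fit_wlls(fw, "DKI", mask = tis$mask)
  vox <- which(tis$mask & fit$fit_ok)
  nvox <- prod(dim(tis$s0))
  d_true <- matrix(tis$d6, nvox, 6)[vox, ]
  d_fit <- matrix(fit$d6, nvox, 6)[vox, ]
  expect_lt(max(abs(d_fit - d_true)) / max(abs(d_true)), 1e-8)
  md <- rowMeans(d_true[, 1:3])
  v_true <- matrix(tis$w15, nvox, 15)[vox, ] * md^2
  v_fit <- matrix(fit$v15, nvox, 15)[vox, ]
  expect_lt(max(abs(v_fit - v_true)) / max(abs(v_true) + 1e-12), 1e-8)
  expect_equal(fit$s0[vox], as.vector(tis$s0)[vox], tolerance = 1e-8)
})

test_that("degenerate voxels are flagged without contaminating neighbours", {
  sch <- mini_scheme(8)
  sig <- array(50, c(5, 5, 5, 10))           # flat across b -> D = 0
  fit0 <- fit_wlls(dwi_dataset(sig, sch), "DTI")
  expect_lt(max(abs(fit0$d6)), 1e-10)
  sig[2, 2, 2, 4] <- 0                        # one zero signal
  fit1 <- fit_wlls(dwi_dataset(sig, sch), "DTI")
  expect_false(fit1$fit_ok[2, 2, 2])
  ok <- fit1$fit_ok; ok[2, 2, 2] <- TRUE
  expect_true(all(ok))
  expect_lt(max(abs(fit1$d6[3, , , ])), 1e-10)
})

test_that("scalar metrics match hand values and have exact invariants", {
  dims <- c(3, 3, 3)
  nv <- prod(dims)
  mkfit <- function(lam, frame = diag(3)) {
    d6 <- tractsens:::mat_to_d6(frame %*% diag(lam) %*% t(frame))
    structure(list(s0 = array(100, dims),
                   d6 = array(rep(d6, each = nv), c(dims, 6)),
                   v15 = array(0, c(dims, 15)),
                   fit_ok = array(TRUE, dims), model = "DKI"),
              class = "diffusion_fit")
  }
  iso <- scalar_metrics(mkfit(c(1, 1, 1) * 1e-3))
  expect_equal(iso$fa[1, 1, 1], 0)
  expect_equal(iso$md[1, 1, 1], 1e-3)
  ani <- scalar_metrics(mkfit(c(1.7, 0.3, 0.3) * 1e-3))
  expect_equal(ani$fa[1, 1, 1], 0.799, tolerance = 1e-3)
  expect_equal(ani$ad[1, 1, 1], 1.7e-3)
  expect_equal(ani$rd[1, 1, 1], 0.3e-3)
  # W = 0 -> all kurtosis metrics 0
  expect_equal(ani$mk[1, 1, 1], 0)
  expect_equal(ani$ak[1, 1, 1], 0)
  expect_equal(ani$rk[1, 1, 1], 0)
  # FA is invariant under scaling of D
  sc <- scalar_metrics(mkfit(c(1.7, 0.3, 0.3) * 3e-3))
  expect_equal(sc$fa[1, 1, 1], ani$fa[1, 1, 1], tolerance = 1e-12)
})

test_that("the kurtosis direction average is converged at the default set", {
  tis <- fix_tissue()
  sch <- protocol_scheme("3T-DKI")
  fit <- fit_wlls(forward_signal(tis, sch), "DKI", mask = tis$mask)
  m1 <- scalar_metrics(fit, direction_set = tractsens:::kurtosis_dirs(64))
  m2 <- scalar_metrics(fit, direction_set = tractsens:::kurtosis_dirs(128))
  vox <- which(tis$mask & fit$fit_ok & abs(m1$mk) > 0.2)
  expect_lt(max(abs(m1$mk[vox] - m2$mk[vox]) / abs(m1$mk[vox])), 0.005)
})

test_that("DTI on the low shells of a DKI scheme equals a native single-shell fit", {
  tis <- fix_tissue()
  dki <- protocol_scheme("3T-DKI")
  keep <- dki$bvalues <= 1000
  sub <- acquisition_scheme(dki$bvalues[keep], dki$directions[keep, ],
                            dki$voxel_size, name = "sub")
  fw_full <- forward_signal(tis, dki)
  fw_sub <- forward_signal(tis, sub)
  fit_a <- fit_wlls(tractsens:::with_signal(
    fw_sub, fw_full$signal[, , , keep, drop = FALSE]), "DTI", mask = tis$mask)
  fit_b <- fit_wlls(fw_sub, "DTI", mask = tis$mask)
  expect_equal(fit_a$d6, fit_b$d6, tolerance = 1e-12)
})
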