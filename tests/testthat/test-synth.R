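# hand-built single-voxel-style tissue with isotropic D and kurtosis K
iso_tissue <- function(dims = c(5, 5, 5), md = 1e-3, k = 0, s0 = 100) {
  nv <- prod(dims)
  d6 <- array(rep(c(md, md, md, 0, 0, 0), each = nv), c(dims, 6))
  idx <- tractsens:::w15_index()
  w <- numeric(15)
  if (k != 0) {
    aaaa <- apply(idx, 1, function(r) length(unique(r)) == 1)
    aabb <- apply(idx, 1, function(r) {
      cnt <- tabulate(r, 3); sum(cnt == 2) == 2
    })
    w[aaaa] <- k
    w[aabb] <- k / 3
  }
  structure(list(s0 = array(s0, dims),
                 d6 = d6,
                 w15 = array(rep(w, each = nv), c(dims, 15)),
                 mask = array(TRUE, dims),
                 truth = NULL),
            class = "tissue_model")
}

test_that("axially symmetric eigenvalues reproduce the FA/MD hand example", {
  eig <- tractsens:::eigs_from_fa_md(0.80, 0.767e-3)
  expect_equal(eig[1], 1.7e-3, tolerance = 0.02)
  expect_equal(eig[2], 0.3e-3, tolerance = 0.05)
  expect_equal(mean(eig), 0.767e-3, tolerance = 1e-10)
  # forward check: FA of (1.7, 0.3, 0.3)e-3 is 0.799
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  fa <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(fa, 0.799, tolerance = 1e-3)
})

test_that("a null design yields identical group tissue distributions", {
  atl <- fix_atlas()
  pop0 <- population_spec(n_hc = 3, n_sle = 3, affected_tracts = "tract01",
                          designed_d = 0)
  hc <- sample_subject(pop0, atl, "HC", seed = 11)
  sle <- sample_subject(pop0, atl, "SLE", seed = 11)
  expect_equal(hc$d6, sle$d6)
  expect_equal(hc$s0, sle$s0)
})

test_that("the designed group shift equals d x between-subject SD exactly", {
  atl <- fix_atlas()
  pop <- population_spec(n_hc = 3, n_sle = 3, affected_tracts = "tract01",
                         parameter = "fa", direction = -1, designed_d = 0.8,
                         between_subject_sd = c(fa = 0.02))
  hc <- sample_subject(pop, atl, "HC", seed = 21)$truth
  sle <- sample_subject(pop, atl, "SLE", seed = 21)$truth
  hit <- hc$tract %in% c("tract01_left", "tract01_right")
  expect_equal(hc$fa[hit] - sle$fa[hit], rep(0.8 * 0.02, sum(hit)))
  expect_equal(hc$fa[!hit], sle$fa[!hit])
})

test_that("forward signals match the cumulant model in closed form", {
  # b = 0 volume equals S0 exactly
  tis <- iso_tissue(md = 1e-3, k = 0)
  sch <- acquisition_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)), 2)
  fw <- forward_signal(tis, sch)
  expect_equal(fw$signal[, , , 1], tis$s0)
  # monoexponential limit: W = 0, b = 1000, D = 1e-3 -> S/S0 = exp(-1)
  expect_equal(fw$signal[3, 3, 3, 2] / 100, exp(-1), tolerance = 1e-12)
  # kurtosis term: D_app = 1e-3, MD = 1e-3, W_app = 1, b = 2750
  tisk <- iso_tissue(md = 1e-3, k = 1)
  schk <- acquisition_scheme(c(0, 2750), rbind(c(0, 0, 0), c(0, 1, 0)), 2)
  fwk <- forward_signal(tisk, schk)
  expect_equal(log(fwk$signal[3, 3, 3, 2] / 100),
               -2.75 + 2750^2 * 1e-6 / 6, tolerance = 1e-9)
})

test_that("attenuation is clipped to stay monotone non-increasing in b", {
  tisk <- iso_tissue(md = 1e-3, k = 2)       # b* = 3D/(MD^2 W) = 1500
  bs <- c(0, 500, 1000, 1500, 2000, 3000)
  sch <- acquisition_scheme(bs, rbind(c(0, 0, 0),
                                      matrix(rep(c(0, 1, 0), 5), 5, 3, byrow = TRUE)), 2)
  s <- forward_signal(tisk, sch)$signal[3, 3, 3, ]
  expect_true(all(diff(s) <= 1e-9))
})

test_that("Rician noise has the closed-form rectified floor", {
  # zero signal, sigma = 1: E|noise| = sqrt(pi/2)
  sch <- acquisition_scheme(0, matrix(0, 1, 3), 2)
  z <- dwi_dataset(array(0, c(100, 100, 100, 1)), sch)
  # sigma = mean positive baseline / snr = 30 / 30 = 1 via one pinned voxel
  z$signal[1, 1, 1, 1] <- 30
  noisy <- add_rician_noise(z, artifact_spec(snr_b0 = 30), seed = 9)
  expect_equal(mean(noisy$signal[-1]), sqrt(pi / 2), tolerance = 0.01)
  # infinite SNR is the identity; fixed seed reproduces the field
  expect_identical(add_rician_noise(z, artifact_spec(snr_b0 = Inf), 1)$signal,
                   z$signal)
  n1 <- add_rician_noise(z, artifact_spec(snr_b0 = 30), seed = 4)
  n2 <- add_rician_noise(z, artifact_spec(snr_b0 = 30), seed = 4)
  expect_identical(n1$signal, n2$signal)
})

test_that("k-space truncation rings sharp edges but spares smooth images", {
  box <- box_dataset()
  g <- apply_gibbs(box, artifact_spec(gibbs_truncation = 0.6))
  mid <- 24
  expect_gt(total_variation(g$signal[, mid, 2, 1]),
            total_variation(box$signal[, mid, 2, 1]))
  # full fraction is the identity
  expect_identical(apply_gibbs(box, artifact_spec(gibbs_truncation = 1))$signal,
                   box$signal)
  # band-limited blob barely changes
  x <- outer(exp(-((1:48) - 24)^2 / 60), exp(-((1:48) - 24)^2 / 60))
  blob <- dwi_dataset(array(rep(x, 3), c(48, 48, 3, 1)) + 1e-9,
                      acquisition_scheme(0, matrix(0, 1, 3), 2))
  gb <- apply_gibbs(blob, artifact_spec(gibbs_truncation = 0.6))
  expect_lt(sqrt(mean((gb$signal - blob$signal)^2)) / max(blob$signal), 0.01)
})

test_that("motion/eddy simulation honours its contracts", {
  tis <- fix_tissue()
  sch <- mini_scheme(6)
  fw <- forward_signal(tis, sch)
  # all ranges zero -> identity
  still <- apply_motion_eddy(fw, artifact_spec(motion_prob = 0), seed = 2)
  expect_identical(still$data$signal, fw$signal)
  # b0 volumes get no eddy component by construction
  art <- artifact_spec(motion_rot_deg = 2, motion_trans_vox = 1, motion_prob = 1,
                       eddy_shear = 0.03, eddy_scale = 0.03)
  me <- apply_motion_eddy(fw, art, seed = 2)
  b0rows <- dplyr::filter(me$transforms, .data$b == 0)
  expect_true(all(b0rows$syx == 0 & b0rows$syz == 0 & b0rows$sy == 1))
  # a pure translation shifts the phase-correlation peak by that amount
  vol <- fw$signal[, , , 3]
  m <- me_matrix(me_params(trans = c(1.5, 0, 0)), dim(vol))
  shifted <- tractsens:::resample_affine(vol, m)
  f1 <- fft(vol); f2 <- fft(shifted)
  r <- f1 * Conj(f2)
  pc <- Re(fft(r / (Mod(r) + 1e-12), inverse = TRUE))
  peak <- which(pc == max(pc), arr.ind = TRUE)[1, ]
  sx <- peak[1] - 1
  if (sx > dim(vol)[1] / 2) sx <- sx - dim(vol)[1]
  expect_true(abs(sx) %in% c(1, 2))  # integer-voxel peak nearest to 1.5
})

test_that("cohort simulation produces the requested design deterministically", {
  atl <- fix_atlas()
  pop <- population_spec(n_hc = 2, n_sle = 3, affected_tracts = "tract01")
  co <- simulate_cohort(pop, atl, mini_scheme(6), artifact_spec(snr_b0 = 50),
                        seed = 9)
  expect_equal(co$design$group, c("HC", "HC", "SLE", "SLE", "SLE"))
  co2 <- simulate_cohort(pop, atl, mini_scheme(6), artifact_spec(snr_b0 = 50),
                         seed = 9)
  expect_identical(co$subjects[[1]]$data$signal, co2$subjects[[1]]$data$signal)
})
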