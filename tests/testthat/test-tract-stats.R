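mk_maps <- function(fa_arr) {
  dims <- dim(fa_arr)
  structure(list(fa = fa_arr, md = array(1e-3, dims), ad = array(1e-3, dims),
                 rd = array(1e-3, dims), fit_ok = array(TRUE, dims),
                 model = "DTI"),
            class = "scalar_maps")
}

test_that("probability-weighted statistics match the hand computation", {
  pr <- array(0, c(2, 2, 2, 1))
  pr[1, 1, 1, 1] <- 0.6; pr[2, 1, 1, 1] <- 0.9
  atl <- tract_atlas(pr, "t1")
  fa <- array(0, c(2, 2, 2)); fa[1, 1, 1] <- 1; fa[2, 1, 1] <- 2
  st <- tract_weighted_stats(mk_maps(fa), atl, prob_floor = 0.5)
  expect_equal(st$value[st$parameter == "fa" & st$feature == "mean"],
               (0.6 * 1 + 0.9 * 2) / 1.5)
  # weighted SD: population form with Sum(p) denominator
  mu <- 1.6
  expect_equal(st$value[st$parameter == "fa" & st$feature == "sd"],
               sqrt((0.6 * (1 - mu)^2 + 0.9 * (2 - mu)^2) / 1.5))
})

test_that("sub-threshold voxels are excluded and constants give SD 0", {
  pr <- array(0, c(3, 3, 3, 1))
  pr[1, 1, 1, 1] <- 0.49                  # just below the floor
  pr[2, 1, 1, 1] <- 0.7
  atl <- tract_atlas(pr, "t1")
  fa <- array(5, c(3, 3, 3)); fa[1, 1, 1] <- 1000
  st <- tract_weighted_stats(mk_maps(fa), atl)
  expect_equal(st$value[st$parameter == "fa" & st$feature == "mean"], 5)
  expect_equal(st$value[st$parameter == "fa" & st$feature == "sd"], 0)
  expect_equal(st$n_voxels[1], 1L)
  # a tract with no qualifying voxel comes back missing, with a message
  pr2 <- pr; pr2[2, 1, 1, 1] <- 0.3
  atl2 <- tract_atlas(pr2, "t1")
  expect_message(st2 <- tract_weighted_stats(mk_maps(fa), atl2), "qualifying")
  expect_true(all(is.na(st2$value)))
})

test_that("weighted means stay inside the included value range", {
  set.seed(8)
  atl <- fix_atlas()
  fa <- array(runif(prod(dim(atl$prob)[1:3])), dim(atl$prob)[1:3])
  st <- tract_weighted_stats(mk_maps(fa), atl)
  for (t in atl$tract_names) {
    sel <- atl$prob[, , , match(t, atl$tract_names)] >= 0.5
    if (!any(sel)) next
    mu <- st$value[st$tract == t & st$parameter == "fa" & st$feature == "mean"]
    expect_gte(mu, min(fa[sel])); expect_lte(mu, max(fa[sel]))
  }
})

test_that("volume CoV flags high-variation tracts with monotone thresholds", {
  base <- array(0, c(8, 8, 8, 1))
  mk_atl <- function(k) {
    p <- base
    p[1:k, 1:3, 1:3, 1] <- 0.9
    tract_atlas(p, "t1")
  }
  atls <- list(A = mk_atl(2), B = mk_atl(2), C = mk_atl(2), D = mk_atl(4))
  design <- tibble::tibble(subject_id = c("A", "B", "C", "D"),
                           group = "HC")
  qc <- tract_volume_cov(atls, design, threshold = 0.25, voxel_size = 2)
  # volumes (18, 18, 18, 36) voxels -> CoV = sd/mean = 9/22.5 = 0.4
  expect_equal(qc$cov, sd(c(18, 18, 18, 36) * 8) / mean(c(18, 18, 18, 36) * 8))
  expect_true(qc$excluded)
  # identical atlases: CoV 0, nothing excluded
  same <- list(A = mk_atl(2), B = mk_atl(2), C = mk_atl(2), D = mk_atl(2))
  qc0 <- tract_volume_cov(same, design, threshold = 0.25)
  expect_equal(qc0$cov, 0)
  expect_false(qc0$excluded)
  # lowering the threshold never un-excludes
  for (thr in c(0.5, 0.39, 0.2, 0.1)) {
    q <- tract_volume_cov(atls, design, threshold = thr)
    if (thr < 0.4) expect_true(q$excluded) else expect_false(q$excluded)
  }
  # zero-volume tract in one control: flagged with a reason
  atls0 <- atls; atls0$A <- tract_atlas(base, "t1")
  q0 <- tract_volume_cov(atls0, design)
  expect_true(q0$excluded)
  expect_match(q0$reason, "zero volume")
  expect_error(tract_volume_cov(atls[1:2], design[1:2, ]), ">= 3")
})

test_that("left/right merging averages pairs and passes midline through", {
  tab <- tibble::tibble(
    subject_id = "s", group = "HC",
    tract = c("arc_left", "arc_right", "cc"),
    parameter = "fa", feature = "mean",
    value = c(0.4, 0.6, 0.33), n_voxels = c(10L, 12L, 20L)
  )
  pr <- array(0.6, c(4, 4, 4, 3))
  atl <- tract_atlas(pr, c("arc_left", "arc_right", "cc"))
  m <- merge_lr(tab, atl)
  expect_equal(m$value[m$tract == "arc"], 0.5)
  expect_equal(m$value[m$tract == "cc"], 0.33)
  expect_equal(nrow(m), 2)
  # a missing side falls back to the available one, with a message
  expect_message(m2 <- merge_lr(dplyr::mutate(tab, value = c(0.4, NA, 0.33)), atl),
                 "single available side")
  expect_equal(m2$value[m2$tract == "arc"], 0.4)
})

test_that("a full 72-tract layout reduces to 41 merged tracts", {
  nm <- c(as.vector(rbind(sprintf("p%02d_left", 1:31), sprintf("p%02d_right", 1:31))),
          sprintf("mid%02d", 1:10))
  tab <- tibble::tibble(subject_id = "s", group = "HC", tract = nm,
                        parameter = "fa", feature = "mean",
                        value = seq_along(nm) / 72, n_voxels = 5L)
  atl <- tract_atlas(array(0.6, c(4, 4, 4, 72)), nm)
  expect_equal(nrow(merge_lr(tab, atl)), 41)
})
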