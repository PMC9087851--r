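test_that("the three study protocols have the documented structure", {
  s1 <- protocol_scheme("3T-DTI")
  s2 <- protocol_scheme("3T-DKI")
  s3 <- protocol_scheme("7T-DTI")
  expect_equal(length(s1), 72)
  expect_equal(sum(scheme_b0(s1)), 8)
  expect_equal(length(s2), 65)
  expect_equal(sum(scheme_b0(s2)), 3)
  expect_equal(scheme_shells(s2), c(250, 500, 1000, 2750))
  expect_equal(length(s3), 33)
  expect_equal(sum(scheme_b0(s3)), 3)
  expect_equal(s1$voxel_size, 2.0)
  expect_equal(s2$voxel_size, 2.3)
  expect_true(scheme_dki_capable(s2))
  expect_false(scheme_dki_capable(s1))
  expect_false(scheme_dki_capable(s3))
})

test_that("scheme invariants are enforced", {
  # diffusion directions must be unit vectors; slight deviations renormalize
  d <- rbind(c(0, 0, 0), c(1 + 5e-4, 0, 0))
  s <- acquisition_scheme(c(0, 1000), d, 2)
  expect_equal(vapply(2, function(i) sqrt(sum(s$directions[i, ]^2)), 1), 1)
  # gross deviation is an error
  expect_error(acquisition_scheme(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0)), 2),
               "unit norm")
  # zero vector accepted as a b0 direction
  expect_silent(acquisition_scheme(0, matrix(0, 1, 3), 2))
  # at least one b0 volume
  expect_error(acquisition_scheme(1000, matrix(c(1, 0, 0), 1), 2), "b=0")
  # length mismatch names both counts
  expect_error(acquisition_scheme(rep(0, 3), matrix(0, 2, 3), 2), "3.*2")
  # small scanner-reported b counts as b0
  expect_true(scheme_b0(acquisition_scheme(c(5, 1000),
                                           rbind(c(0, 0, 0), c(1, 0, 0)), 2))[1])
})

test_that("direction subsampling reduces the top shell", {
  s <- protocol_scheme("3T-DTI", n_directions = 30)
  expect_equal(length(s), 38)
  expect_equal(sum(s$bvalues == 1000), 30)
})
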