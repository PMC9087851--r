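test_that("the synthetic atlas generator is deterministic with mirrored pairs", {
  a1 <- build_atlas(c(24, 24, 24), 6, seed = 7)
  a2 <- build_atlas(c(24, 24, 24), 6, seed = 7)
  expect_identical(a1$prob, a2$prob)
  # 6 tracts -> 2 mirrored pairs + 2 midline
  expect_equal(sum(!is.na(a1$laterality$pair)), 4)
  expect_equal(sum(a1$laterality$side == "midline"), 2)
  # mirrored pair maps are exact x-reflections of each other
  left <- a1$prob[, , , 1]
  right <- a1$prob[, , , 2]
  expect_equal(right, left[rev(seq_len(24)), , ])
  # probabilities bounded with soft edges
  expect_true(all(a1$prob >= 0 & a1$prob <= 1))
  expect_true(any(a1$prob > 0 & a1$prob < 0.5))
  # no degenerate (empty) tract
  expect_false(any(a1$laterality$empty))
})

test_that("a single tract occupies a minority of a minimal grid", {
  a <- build_atlas(c(16, 16, 16), 1, seed = 3)
  expect_lt(mean(a$prob[, , , 1] >= 0.5), 0.5)
})

test_that("atlas pairing is an involution and validation catches bad input", {
  a <- fix_atlas()
  lat <- a$laterality
  for (i in seq_len(nrow(lat))) {
    if (is.na(lat$pair[i])) next
    j <- match(lat$pair[i], lat$tract)
    expect_identical(lat$pair[j], lat$tract[i])
  }
  expect_error(tract_atlas(array(1.5, c(4, 4, 4, 1)), "x"), "outside")
  expect_error(tract_atlas(array(0.5, c(4, 4, 4, 1)), c("x", "y")), "names")
  # dangling pair reference
  expect_error(tract_atlas(array(0.5, c(4, 4, 4, 2)), c("a", "b"),
                           laterality = c("left", "right"),
                           pair = c("zzz", "a")),
               "unknown|symmetric")
})

test_that("absurd packing requests are refused", {
  expect_error(build_atlas(c(16, 16, 16), 60, seed = 1), "pack")
})
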