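test_that("two-shell protocol layout matches the acquisition design", {
  gt <- two_shell_gtab()
  expect_length(gt$bvals, 138)            # 10 b=0 + 2 x 64 directions
  expect_equal(length(gt$shell_bvals), 2)
  expect_equal(sort(gt$shell_bvals), c(1500, 3000))
  expect_equal(sum(gt$bvals == 0), 10)
  nz <- gt$bvals > 0
  expect_true(all(abs(sqrt(rowSums(gt$bvecs[nz, ]^2)) - 1) < 1e-6))
  expect_true(all(gt$bvecs[!nz, ] == 0))
})

test_that("direction layouts are distinct, balanced and deterministic", {
  gt <- make_gradient_table(1, 6, 1000)
  expect_length(gt$bvals, 7)
  d <- gt$bvecs[gt$bvals > 0, ]
  ang <- acos(pmin(1, abs(tcrossprod(d))))[upper.tri(diag(6))]
  expect_true(min(ang) > 0)

  g2 <- make_gradient_table(0, 64, 3000)
  expect_lt(sqrt(sum(colMeans(g2$bvecs)^2)), 0.2)   # near-uniform over S^2

  g3 <- make_gradient_table(0, 64, 3000)
  expect_identical(g2$bvecs, g3$bvecs)
})

test_that("shells cluster within +/- 50 s/mm^2 and inputs are validated", {
  gt <- gradient_table(c(0, 995, 1005, 2990, 3010),
                       rbind(0, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                             c(1, 1, 0) / sqrt(2)))
  expect_equal(length(gt$shell_bvals), 2)
  expect_equal(gt$shell_of, c(0L, 1L, 1L, 2L, 2L))

  expect_error(make_gradient_table(1, 6, c(-100)), "positive")
  expect_error(make_gradient_table(1, 6, c(1000, 1000)), "distinct")
  expect_error(make_gradient_table(1, 3, 1000), "at least 6")
  expect_error(gradient_table(c(0, 1000), rbind(c(0, 0, 0))), "format error")
})
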