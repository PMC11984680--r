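test_that("single-voxel forward model matches closed forms", {
  gt <- make_gradient_table(1, 6, 3000)
  s <- simulate_voxel_signal(gt, c(1, 0, 0))      # pure free water
  expect_equal(s[1], 1)
  expect_equal(unique(round(s[-1], 12)), round(exp(-9), 12))

  s2 <- simulate_voxel_signal(gradient_table(c(0, 3000),
                                             rbind(0, c(0, 0, 1))),
                              c(0, 0, 1), fiber_dir = c(0, 0, 1))
  expect_equal(s2[2], exp(-3000 * 1.7e-3))        # g parallel to v: exp(-5.1)

  # linearity of the mixture (noiseless)
  gt2 <- two_shell_gtab()
  v <- c(0, 0, 1)
  mix <- simulate_voxel_signal(gt2, c(0.5, 0, 0.5), v)
  pure <- 0.5 * simulate_voxel_signal(gt2, c(1, 0, 0)) +
    0.5 * simulate_voxel_signal(gt2, c(0, 0, 1), v)
  expect_equal(mix, pure, tolerance = 1e-12)

  expect_error(simulate_voxel_signal(gt, c(0, 0.5, 0.5)), "fiber_dir")
  expect_error(simulate_voxel_signal(gt, c(0.6, 0.6, 0)), "sum to 1")
})

test_that("phantom rasterization records exact ground truth", {
  ph <- small_phantom()
  tr <- ph$truth
  # every bundle voxel carries the z direction
  bundle <- tr$tissue_masks$wm
  dirs <- matrix(tr$fiber_direction, ncol = 3)[which(bundle), ]
  expect_true(all(abs(dirs[, 3]) > 1 - 1e-9))
  # fraction triples sum to 1 everywhere
  fr <- matrix(tr$true_fractions, ncol = 3)
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # fiber direction defined wherever true f_ICA > 0
  expect_true(all(!is.na(dirs)))
  has_ica <- fr[, 3] > 0
  expect_true(all(!is.na(matrix(tr$fiber_direction, ncol = 3)[has_ica, 1])))
})

test_that("lesion rasterization equals brute-force sphere counting", {
  vs <- 1.7
  spec <- phantom_spec(grid_shape = c(9, 9, 9), voxel_size = vs,
                       lesions = list(lesion_spec(c(7.65, 7.65, 7.65),
                                                  radius_mm = 2 * vs,
                                                  fractions = c(.6, .4, 0))))
  ph <- build_phantom(spec, make_gradient_table(1, 6, 1000))
  ctr <- lesionometry:::voxel_centers(c(9, 9, 9),
                                      lesionometry:::make_affine(vs))
  d <- sqrt(rowSums(sweep(ctr, 2, c(7.65, 7.65, 7.65))^2))
  expect_equal(sum(ph$truth$wmh_mask), sum(d <= 2 * vs))

  spec0 <- phantom_spec(grid_shape = c(5, 5, 5))
  ph0 <- build_phantom(spec0, make_gradient_table(1, 6, 1000))
  expect_true(all(!ph0$truth$wmh_mask))
})

test_that("noiseless b0 is exactly 1 and generation is bit-reproducible", {
  ph <- small_phantom()
  b0 <- ph$dwi$data[, , , which(ph$dwi$gtab$bvals == 0)[1]]
  expect_true(all(abs(b0[ph$dwi$brain_mask] - 1) < 1e-12))

  spec <- phantom_spec(grid_shape = c(6, 6, 6), snr = 20, seed = 9L)
  gt <- make_gradient_table(2, 6, 1000)
  a <- build_phantom(spec, gt)
  b <- build_phantom(spec, gt)
  expect_identical(a$dwi$data, b$dwi$data)
})

test_that("Rician noise biases the b0 mean upward, vanishing as SNR grows", {
  gt <- make_gradient_table(500, 6, 1000)
  bias <- sapply(c(2, 10), function(snr) {
    set.seed(4)
    mean(replicate(40, mean(simulate_voxel_signal(
      gt, c(1, 0, 0), snr = snr)[gt$bvals == 0]))) - 1
  })
  expect_gt(bias[1], 0.05)       # strong Rician bias at SNR 2
  expect_gt(bias[2], 0)          # still positive at SNR 10 ...
  expect_lt(bias[2], bias[1] / 5) # ... but shrinking toward zero
})

test_that("overlapping bundles renormalize and the dominant direction wins", {
  vs <- 1
  b1 <- bundle_spec(rbind(c(3, 3, 0), c(3, 3, 6)), radius_mm = 1.4,
                    fractions = c(0, 0.2, 0.8))
  b2 <- bundle_spec(rbind(c(0, 3, 3), c(6, 3, 3)), radius_mm = 1.4,
                    fractions = c(0, 0.6, 0.4))
  spec <- phantom_spec(grid_shape = c(6, 6, 6), voxel_size = vs,
                       bundles = list(b1, b2))
  ph <- build_phantom(spec, make_gradient_table(1, 6, 1000))
  fr <- matrix(ph$truth$true_fractions, ncol = 3)
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # the crossing voxel blends the two fraction triples and keeps b1's axis
  cross <- ph$truth$fiber_direction[4, 4, 4, ]
  expect_gt(abs(cross[3]), 1 - 1e-9)
  expect_equal(ph$truth$true_fractions[4, 4, 4, ],
               (c(0, .2, .8) + c(0, .6, .4)) / 2)
})
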