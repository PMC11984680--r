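test_that("seed points are uniform over the in-mask voxel volume", {
  mask <- array(FALSE, c(4, 4, 4)); mask[2, 3, 4] <- TRUE
  af <- lesionometry:::make_affine(2)
  set.seed(1)
  p <- seed_points(mask, 50, af)
  g <- lesionometry:::world_to_grid(af, p)
  expect_true(all(floor(g[, 1]) == 1 & floor(g[, 2]) == 2 &
                    floor(g[, 3]) == 3))

  set.seed(7); a <- seed_points(mask, 10, af)
  set.seed(7); b <- seed_points(mask, 10, af)
  expect_identical(a, b)

  # uniform mask: per-voxel counts within 4 sigma of the multinomial
  mask2 <- array(TRUE, c(3, 3, 3))
  set.seed(2)
  g2 <- floor(lesionometry:::world_to_grid(af, seed_points(mask2, 27000, af)))
  counts <- table(factor(g2[, 1] + 3 * g2[, 2] + 9 * g2[, 3],
                         levels = 0:26))
  expected <- 27000 / 27
  expect_true(all(abs(counts - expected) <
                    4 * sqrt(expected * (1 - 1 / 27))))

  expect_error(seed_points(array(FALSE, c(2, 2, 2)), 5, af), "empty mask")
})

test_that("propagation rejects degenerate fields and honors the length filter", {
  dims <- c(6, 6, 6)
  zero_fod <- structure(list(coef = array(0, c(dims, 15)),
                             affine = lesionometry:::make_affine(1.7),
                             lmax = 4, mask = array(TRUE, dims)),
                        class = "fod_field")
  expect_null(propagate_streamline(zero_fod, c(5, 5, 5)))
  expect_error(generate_tractogram(zero_fod,
                                   params = tracking_params(target_count = 50)),
               "degenerate")
})

test_that("bundle-phantom streamlines follow the fiber and the filter", {
  dfit <- default_fit()
  tp <- tracking_params(target_count = 500)
  tr <- generate_tractogram(dfit$fit$fod, dfit$dwi$brain_mask, tp, seed = 3)
  expect_length(tr$streamlines, 500)
  expect_gte(min(streamline_lengths(tr)), 2.6)
  # consecutive points separated by exactly one step
  steps <- lapply(tr$streamlines[1:20], function(p)
    sqrt(rowSums(diff(p)^2)))
  expect_true(all(abs(unlist(steps) - tp$step_size) < 1e-6))
  # alignment with the generating +/- z axis
  al <- vapply(tr$streamlines, function(p) {
    d <- diff(p); m <- colMeans(d / sqrt(rowSums(d^2)))
    abs(m[3] / sqrt(sum(m^2)))
  }, 0)
  expect_gte(mean(acos(pmin(al, 1)) * 180 / pi < 15), 0.9)

  tr2 <- generate_tractogram(dfit$fit$fod, dfit$dwi$brain_mask, tp, seed = 3)
  expect_identical(tr$streamlines, tr2$streamlines)
})

test_that("acceptance rate is consistent across disjoint seed batches", {
  dfit <- default_fit()
  tp <- tracking_params(target_count = 400)
  t1 <- generate_tractogram(dfit$fit$fod, dfit$dwi$brain_mask, tp, seed = 11)
  t2 <- generate_tractogram(dfit$fit$fod, dfit$dwi$brain_mask, tp, seed = 12)
  p1 <- 400 / t1$seed_count
  p2 <- 400 / t2$seed_count
  se <- sqrt(p1 * (1 - p1) / t1$seed_count + p2 * (1 - p2) / t2$seed_count)
  expect_lt(abs(p1 - p2), 5 * se + 1e-9)
})

test_that("track density counts distinct streamlines per voxel", {
  af <- lesionometry:::make_affine(1)
  dims <- c(7, 7, 7)
  # one axis-aligned streamline crossing exactly 5 voxels
  sl <- line_through(c(1.2, 3.5, 3.5), c(5.8, 3.5, 3.5))
  td <- track_density_map(toy_tractogram(list(sl), af), dims)
  expect_equal(sum(td == 1), 5)
  expect_equal(sum(td), 5)
  expect_true(all(which(td == 1, arr.ind = TRUE)[, 2] == 4))

  td2 <- track_density_map(toy_tractogram(list(sl, sl), af), dims)
  expect_true(all(td2[td == 1] == 2))
  expect_equal(sum(td2), 10)
})

test_that("exact traversal equals the dense point-membership oracle", {
  set.seed(33)
  af <- lesionometry:::make_affine(1.7)
  dims <- c(8, 8, 8)
  sl <- lapply(1:50, function(i) {
    p0 <- runif(3, 2, 11)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    t(sapply(0:9, function(k) p0 + k * 0.45 * d))
  })
  got <- streamline_voxels(toy_tractogram(sl, af), dims)
  want <- oracle_streamline_voxels(sl, dims, af)
  expect_identical(lapply(got, function(v) as.integer(sort(v))), want)
})
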