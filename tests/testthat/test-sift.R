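test_that("degenerate keep counts are validated; identity at full keep", {
  af <- lesionometry:::make_affine(1)
  sl <- list(line_through(c(0.5, 0.5, 0.5), c(3.5, 0.5, 0.5)))
  fod <- structure(list(coef = array(0.1, c(4, 4, 4, 15)), affine = af,
                        lmax = 4, mask = array(TRUE, c(4, 4, 4))),
                   class = "fod_field")
  tr <- toy_tractogram(sl, af)
  expect_error(sift_filter(tr, fod, 0), "positive")
  expect_error(sift_filter(tr, fod, 5), "exceeds")
  expect_identical(sift_filter(tr, fod, 1)$streamlines, sl)
})

test_that("greedy removal matches exhaustive search on the duplicate toy", {
  af <- lesionometry:::make_affine(1)
  dims <- c(6, 3, 3)
  # 10 duplicates over-supplying one voxel; 1 lone streamline elsewhere
  dup <- line_through(c(1.5, 0.5, 0.5), c(1.5, 2.5, 0.5), n = 4)
  lone <- line_through(c(4.5, 0.5, 0.5), c(4.5, 2.5, 0.5), n = 4)
  sl <- c(rep(list(dup), 10), list(lone))
  coef <- array(0, c(dims, 15))
  coef[, , , 1] <- 0.3 * sqrt(4 * pi)   # uniform mean amplitude 0.3
  fod <- structure(list(coef = coef, affine = af, lmax = 4,
                        mask = array(TRUE, dims)), class = "fod_field")
  tr <- toy_tractogram(sl, af)
  kept <- sift_filter(tr, fod, 5)
  expect_length(kept$streamlines, 5)
  # the lone streamline survives; only duplicates are removed
  expect_true(any(vapply(kept$streamlines, function(p)
    isTRUE(all.equal(p, lone)), TRUE)))

  # exhaustive oracle over kept compositions (duplicates interchangeable):
  # cost of keeping k duplicates and m lone copies, mu optimally refit
  vox <- streamline_voxels(tr, dims)
  amp <- as.numeric(fod$coef[, , , 1]) / sqrt(4 * pi)
  allvox <- sort(unique(unlist(vox)))
  cost_of <- function(k_dup, k_lone) {
    td <- k_dup * tabulate(vox[[1]], nbins = prod(dims)) +
      k_lone * tabulate(vox[[11]], nbins = prod(dims))
    td <- td[allvox]
    a <- amp[allvox]
    mu <- if (sum(td^2) > 0) sum(a * td) / sum(td^2) else 0
    sum((mu * td - a)^2)
  }
  best <- min(mapply(cost_of, k_dup = 4:5, k_lone = 1:0))
  n_dup_kept <- sum(vapply(kept$streamlines, function(p)
    isTRUE(all.equal(p, dup)), TRUE))
  got <- cost_of(n_dup_kept, 5 - n_dup_kept)
  expect_equal(got, best, tolerance = 1e-12)
  expect_equal(n_dup_kept, 4)
})

test_that("cost is non-increasing and pruning tightens the TD-FOD coupling", {
  dfit <- default_fit()
  tr <- generate_tractogram(dfit$fit$fod, dfit$dwi$brain_mask,
                            tracking_params(target_count = 1500), seed = 5)
  pruned <- sift_filter(tr, dfit$fit$fod, 300)
  cost <- attr(pruned, "sift_cost")
  expect_true(all(diff(cost) <= 1e-9))
  expect_length(pruned$streamlines, 300)
  # subset property
  expect_true(all(vapply(pruned$streamlines, function(p)
    any(vapply(tr$streamlines, function(q) identical(p, q), TRUE)), TRUE)))

  dims <- dim(dfit$dwi$brain_mask)
  bundle <- dfit$truth$tissue_masks$wm | dfit$truth$penumbra_mask |
    dfit$truth$wmh_mask
  f00 <- dfit$fit$fod$coef[, , , 1]
  c_pre <- cor(as.vector(track_density_map(tr, dims)[bundle]),
               as.vector(f00[bundle]))
  c_post <- cor(as.vector(track_density_map(pruned, dims)[bundle]),
                as.vector(f00[bundle]))
  expect_gt(c_post, c_pre)
})
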