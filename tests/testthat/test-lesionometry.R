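## toy geometry shared across blocks: 8^3 grid at 1 mm, streamlines built
## through known voxel centres
les_affine <- lesionometry:::make_affine(1)
les_dims <- c(8, 8, 8)

wmh_at <- function(ijk) {
  m <- array(FALSE, les_dims)
  m[ijk[1], ijk[2], ijk[3]] <- TRUE
  lesion_mask(m, les_affine)
}

test_that("streamline selection matches membership semantics exactly", {
  set.seed(8)
  sl <- lapply(1:40, function(i) {
    p0 <- runif(3, 1, 7); d <- rnorm(3); d <- d / sqrt(sum(d^2))
    t(sapply(0:7, function(k) p0 + k * 0.4 * d))
  })
  tr <- toy_tractogram(sl, les_affine)
  wmh <- wmh_at(c(4, 4, 4))

  sel <- select_lesioned_streamlines(tr, wmh)
  # brute-force oracle: dense point sampling membership
  ovox <- oracle_streamline_voxels(sl, les_dims, les_affine)
  widx <- which(wmh$mask)
  want <- which(vapply(ovox, function(v) any(v %in% widx), TRUE))
  expect_identical(attr(sel, "selected"), want)

  # empty mask -> empty subset; full mask -> identity
  none <- lesion_mask(array(FALSE, les_dims), les_affine)
  expect_length(select_lesioned_streamlines(tr, none)$streamlines, 0)
  all_m <- lesion_mask(array(TRUE, les_dims), les_affine)
  expect_identical(select_lesioned_streamlines(tr, all_m)$streamlines, sl)

  # monotonicity: A subset of B implies selection(A) subset of selection(B)
  bigger <- wmh$mask; bigger[2, 2, 2] <- TRUE
  selB <- select_lesioned_streamlines(tr, lesion_mask(bigger, les_affine))
  expect_true(all(attr(sel, "selected") %in% attr(selB, "selected")))

  bad <- lesion_mask(wmh$mask, lesionometry:::make_affine(2))
  expect_error(select_lesioned_streamlines(tr, bad), "alignment")
})

test_that("the 10-tract threshold and WMH exclusion are exact", {
  wmh <- wmh_at(c(3, 4, 4))
  # every streamline passes through the WMH voxel (3,4,4) [1-based];
  # 10 continue through voxel A = (6,4,4), 9 through B = (6,6,4) via y-turnless
  # separate straight lines, 50 through the WMH only
  through <- function(target_ctr, n) {
    lapply(seq_len(n), function(i)
      line_through(c(2.5, 3.5, 3.5), target_ctr, n = 10))
  }
  slA <- through(c(5.5, 3.5, 3.5), 10)          # crosses A
  slB <- lapply(seq_len(9), function(i)         # crosses B
    line_through(c(2.5, 3.5, 3.5), c(5.5, 5.5, 3.5), n = 10))
  slW <- lapply(seq_len(50), function(i)        # stays inside the WMH voxel
    line_through(c(2.2, 3.5, 3.5), c(2.8, 3.5, 3.5), n = 4))
  tr <- toy_tractogram(c(slA, slB, slW), les_affine)

  subset <- select_lesioned_streamlines(tr, wmh)
  expect_length(subset$streamlines, 69)
  roi <- build_lesionometry_roi(subset, wmh, min_tracts = 10)

  idx <- which(roi$mask, arr.ind = TRUE)
  expect_true(all(!roi$mask[3, 4, 4]))          # WMH excluded despite TD 69
  expect_true(roi$mask[6, 4, 4])                # 10 tracts: included
  expect_false(roi$mask[6, 6, 4])               # 9 tracts: excluded

  # raising the threshold never grows the ROI
  roi11 <- build_lesionometry_roi(subset, wmh, min_tracts = 11)
  expect_true(all(roi11$mask <= roi$mask))
  expect_error(build_lesionometry_roi(subset, wmh, 0), "min_tracts")

  empty <- select_lesioned_streamlines(toy_tractogram(list(), les_affine),
                                       wmh)
  roi0 <- build_lesionometry_roi(empty, wmh, 10)
  expect_true(roi0$empty)
  expect_equal(roi0$volume_mm3, 0)
})

test_that("ROI statistics are unweighted voxel means of the fractions", {
  wmh <- wmh_at(c(2, 2, 2))
  sl <- lapply(1:12, function(i)
    line_through(c(1.5, 1.5, 1.5), c(5.5, 1.5, 1.5), n = 10))
  subset <- select_lesioned_streamlines(toy_tractogram(sl, les_affine), wmh)
  roi <- build_lesionometry_roi(subset, wmh, 10)
  expect_gt(sum(roi$mask), 0)

  f <- array(NA_real_, c(les_dims, 3))
  f[, , , 1] <- 0.1; f[, , , 2] <- 0.2; f[, , , 3] <- 0.7
  fr <- structure(list(f = f, affine = les_affine), class = "fraction_field")
  roi <- roi_statistics(roi, fr)
  expect_equal(c(roi$mean_f_ECI, roi$mean_f_ICI, roi$mean_f_ICA),
               c(0.1, 0.2, 0.7))
  expect_equal(roi$mean_f_ECI + roi$mean_f_ICI + roi$mean_f_ICA, 1,
               tolerance = 1e-6)

  # two-voxel mean of distinct rows
  roi2 <- roi
  roi2$mask[] <- FALSE; roi2$mask[5, 5, 5] <- TRUE; roi2$mask[6, 5, 5] <- TRUE
  roi2$empty <- FALSE
  f2 <- f
  f2[5, 5, 5, ] <- c(1, 0, 0); f2[6, 5, 5, ] <- c(0, 0, 1)
  fr2 <- structure(list(f = f2, affine = les_affine),
                   class = "fraction_field")
  roi2 <- roi_statistics(roi2, fr2)
  expect_equal(c(roi2$mean_f_ECI, roi2$mean_f_ICI, roi2$mean_f_ICA),
               c(0.5, 0, 0.5))
})

test_that("lesion load is the WMH/ROI volume ratio with safe edge cases", {
  af <- lesionometry:::make_affine(1)
  mk_roi <- function(n) {
    m <- array(FALSE, c(12, 12, 12)); m[seq_len(n)] <- TRUE
    structure(list(mask = m, affine = af, min_tracts = 10L,
                   volume_mm3 = n, lesion_load = NA, mean_f_ECI = NA,
                   mean_f_ICI = NA, mean_f_ICA = NA, empty = n == 0),
              class = "lesionometry_roi")
  }
  wmh100 <- lesion_mask(array(rep(c(TRUE, FALSE), c(100, 1628)),
                              c(12, 12, 12)), af)
  expect_equal(lesion_load(wmh100, mk_roi(1000)), 0.1)
  wmh0 <- lesion_mask(array(FALSE, c(12, 12, 12)), af)
  expect_equal(lesion_load(wmh0, mk_roi(1000)), 0)
  expect_true(is.na(lesion_load(wmh100, mk_roi(0))))
})

test_that("on the lesioned bundle the ROI extends beyond the lesion", {
  dfit <- default_fit()
  wmh <- lesion_mask(dfit$truth$wmh_mask, dfit$truth$affine)
  tr <- generate_tractogram(dfit$fit$fod, dfit$dwi$brain_mask,
                            tracking_params(target_count = 800), seed = 2)
  subset <- select_lesioned_streamlines(tr, wmh)
  roi <- build_lesionometry_roi(subset, wmh, 10)
  expect_false(roi$empty)
  expect_true(all(!(roi$mask & wmh$mask)))
  # the lesion sits mid-bundle; the ROI reaches z slices the lesion misses
  z_roi <- range(which(apply(roi$mask, 3, any)))
  z_wmh <- range(which(apply(wmh$mask, 3, any)))
  expect_true(z_roi[1] < z_wmh[1] && z_roi[2] > z_wmh[2])
  ll <- lesion_load(wmh, roi)
  expect_equal(ll, sum(wmh$mask) / sum(roi$mask))
})
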