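test_that("real even SH basis has the right shape and normalization", {
  b0 <- sh_basis(rbind(c(0.3, -0.4, 0.866)), 0)
  expect_equal(ncol(b0$matrix), 1)
  expect_equal(b0$matrix[1, 1], 1 / sqrt(4 * pi))

  expect_equal(ncol(sh_basis(rbind(c(0, 0, 1)), 8)$matrix), 45)
  expect_error(sh_basis(rbind(c(0, 0, 1)), 5), "even")

  # numerical orthonormality over a dense quadrature
  dd <- sphere_directions(5000)
  B <- sh_basis(dd, 8)$matrix
  G <- crossprod(B) * (4 * pi / 5000)
  expect_lt(max(abs(G - diag(45))), 1e-3)
})

test_that("amplitudes are antipodally symmetric and the C++ path agrees", {
  set.seed(1)
  d <- matrix(rnorm(60), 20)
  d <- d / sqrt(rowSums(d^2))
  fod <- rnorm(45)
  expect_equal(fod_amplitude(fod, d, clip = FALSE),
               fod_amplitude(fod, -d, clip = FALSE), tolerance = 1e-12)
  expect_lt(max(abs(sh_basis(d, 8)$matrix -
                      lesionometry:::cpp_sh_eval(d, 8))), 1e-12)
})

test_that("l = 0-only FODs are isotropic and zonal FODs peak on-axis", {
  iso <- c(2, rep(0, 44))
  amp <- fod_amplitude(iso, sphere_directions(100))
  expect_lt(diff(range(amp)), 1e-12)

  zon <- numeric(45)
  zon[zonal_idx <- which(sh_lm(8)$m == 0)] <- c(1, 0.8, 0.5, 0.3, 0.1)
  dense <- sphere_directions(2000)
  a <- fod_amplitude(zon, dense, clip = FALSE)
  peak <- dense[which.max(a), ]
  expect_lt(acos(min(1, abs(peak[3]))) * 180 / pi, 5)
})
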