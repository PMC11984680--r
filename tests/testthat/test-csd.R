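test_that("pure compartments are recovered from noiseless signal", {
  gt <- two_shell_gtab()
  resp <- small_responses()
  v <- c(0, 0, 1)

  wm <- fit_ss3t(simulate_voxel_signal(gt, c(0, 0, 1), v), gt, resp)
  expect_gte(wm$fractions[["f_ICA"]], 0.90)        # healthy-WM bound
  expect_lt(acos(min(1, abs(fod_peak(wm$fod)[3]))) * 180 / pi, 10)

  csf <- fit_ss3t(simulate_voxel_signal(gt, c(1, 0, 0)), gt, resp)
  expect_gte(csf$fractions[["f_ECI"]], 0.95)
  expect_lt(sum(csf$fod[-1]^2), 1e-6)              # no angular structure

  mix <- fit_ss3t(simulate_voxel_signal(gt, c(0.5, 0, 0.5), v), gt, resp)
  expect_lt(max(abs(mix$fractions - c(0.5, 0, 0.5))), 0.05)
})

test_that("noiseless fraction grid recovers within 0.05 per compartment", {
  gt <- two_shell_gtab()
  resp <- small_responses()
  v <- c(0, 0, 1)
  grid <- expand.grid(e = seq(0, 1, 0.1), i = seq(0, 1, 0.1))
  grid <- grid[grid$e + grid$i <= 1 + 1e-9, ]
  grid$a <- round(1 - grid$e - grid$i, 10)
  sig <- t(apply(grid, 1, function(r)
    simulate_voxel_signal(gt, c(r[["e"]], r[["i"]], r[["a"]]), v)))
  fr <- matrix(fit_voxels(sig, gt, resp)$fractions$f, ncol = 3)
  err <- abs(fr - as.matrix(grid[, c("e", "i", "a")]))
  expect_lt(mean(err[, 1]), 0.05)
  expect_lt(mean(err[, 2]), 0.05)
  expect_lt(mean(err[, 3]), 0.05)
})

test_that("recovered free water is monotone in generating free water", {
  gt <- two_shell_gtab()
  resp <- small_responses()
  v <- c(0, 0, 1)
  fe <- seq(0, 1, 0.1)
  sig <- t(sapply(fe, function(x)
    simulate_voxel_signal(gt, c(x, (1 - x) * 0.3, (1 - x) * 0.7), v)))
  rec <- matrix(fit_voxels(sig, gt, resp)$fractions$f, ncol = 3)[, 1]
  expect_true(all(diff(rec) >= -1e-6))
})

test_that("orientation is recovered within 10 degrees at random axes", {
  gt <- two_shell_gtab()
  resp <- small_responses()
  set.seed(21)
  for (k in 1:8) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    f <- fit_ss3t(simulate_voxel_signal(gt, c(0.1, 0, 0.9), v), gt, resp)
    ang <- acos(min(1, abs(sum(fod_peak(f$fod) * v)))) * 180 / pi
    expect_lt(ang, 10)
  }
})

test_that("FOD amplitudes respect the non-negativity tolerance", {
  gt <- two_shell_gtab()
  resp <- small_responses()
  f <- fit_ss3t(simulate_voxel_signal(gt, c(0.2, 0.2, 0.6), c(0, 0, 1)),
                gt, resp)
  amp <- fod_amplitude(f$fod, sphere_directions(2000), clip = FALSE)
  expect_gte(min(amp), -1e-4)
})

test_that("stochastic recovery at SNR 30 stays within the stated bound", {
  gt <- two_shell_gtab()
  resp <- small_responses()
  v <- c(0, 0, 1)
  set.seed(1)
  truth <- t(replicate(500, { x <- runif(3); x / sum(x) }))
  sig <- t(sapply(seq_len(500), function(i)
    simulate_voxel_signal(gt, truth[i, ], v, snr = 30)))
  fr <- matrix(fit_voxels(sig, gt, resp)$fractions$f, ncol = 3)
  med <- apply(abs(fr - truth), 2, median)
  expect_lt(med[1], 0.10)
  expect_lt(med[2], 0.10)
  expect_lt(med[3], 0.10)
})

test_that("signal_fractions normalizes and flags degenerate voxels", {
  expect_equal(drop(signal_fractions(rbind(c(2, 1, 1)))),
               c(f_ECI = 0.25, f_ICI = 0.25, f_ICA = 0.5))
  expect_equal(unname(drop(signal_fractions(rbind(c(0, 0, 5))))),
               c(1, 0, 0))
  set.seed(2)
  w <- matrix(runif(30), 10)
  expect_true(all(abs(rowSums(signal_fractions(w)) - 1) < 1e-12))
  expect_true(all(is.na(signal_fractions(rbind(c(0, 0, 0))))))
  expect_error(signal_fractions(rbind(c(-1, 1, 1))), "negative")
})

test_that("under-determined direction sets are rejected", {
  gt <- make_gradient_table(2, 6, 3000)
  ph <- small_phantom()
  resp <- small_responses()
  sig <- simulate_voxel_signal(gt, c(0, 0, 1), c(0, 0, 1))
  expect_error(fit_ss3t(sig, gt, resp, ss3t_options(lmax = 8)),
               "rank-deficient")
})
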