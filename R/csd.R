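## Single-shell 3-tissue constrained spherical deconvolution (SS3T-CSD).
## Per voxel, solves min || A x - s ||^2 over x = (FOD SH coefficients,
## w_ICI, w_ECI) subject to FOD amplitude >= 0 on a dense direction set and
## w_ICI, w_ECI >= 0, where A concatenates (over the b = 0 set and the
## outermost shell) the rotational-harmonic convolution of the WM response
## with the FOD and normalized per-shell isotropic response columns. The
## solver is an exact Lawson-Hanson inequality-constrained least squares
## (LSI via LDP/NNLS). The single-shell GM/CSF degeneracy - one GM unit is
## exactly mimicked by a non-negative WM-FOD pedestal + CSF combination -
## is resolved by a tiny ridge on the FOD l = 0 coefficient, selecting the
## minimal-pedestal (maximal-GM) point of the optimal set. Weights are in
## b0-signal units, so signal fractions follow by normalization:
## f_ICA = w_ICA / (w_ICA + w_ICI + w_ECI), etc., with
## w_ICA = wm_b0_amplitude * sqrt(4 pi) * (FOD l = 0 coefficient).

#' Default options for the SS3T fit
#'
#' @param lmax even FOD harmonic order (default 8; 45 coefficients, suited
#'   to 64 directions at b = 3000 s/mm^2).
#' @param n_constraint number of quasi-uniform directions on which FOD
#'   non-negativity is enforced as hard inequality constraints.
#' @param eps non-negativity tolerance on fitted amplitudes.
#' @param max_iter iteration cap of the NNLS inner solver.
#' @param f00_ridge ridge weight on the FOD l = 0 coefficient (in b0-signal
#'   units); the degeneracy tie-break. Small enough not to perturb
#'   well-posed fits.
#' @param rician_correction apply the moment-based Rician bias correction
#'   `s <- sqrt(max(s^2 - 2 sigma^2, 0))` with `sigma` estimated from the
#'   spread of the b = 0 repeats (a no-op on noiseless data). Without it
#'   the b = 3000 noise floor masquerades as GM-like signal and biases the
#'   isotropic split.
#' @return list of options.
#' @export
ss3t_options <- function(lmax = 8, n_constraint = 300, eps = 1e-4,
                         max_iter = 300, f00_ridge = 1e-3,
                         rician_correction = TRUE) {
  if (lmax %% 2 != 0) stop_invalid("lmax must be even")
  list(lmax = lmax, n_constraint = n_constraint, eps = eps,
       max_iter = max_iter, f00_ridge = f00_ridge,
       rician_correction = rician_correction)
}

## sigma estimate from b0 repeats (rows of `sig` are voxels); moment
## correction for Rician magnitude bias
rician_correct <- function(sig, b0_cols) {
  if (length(b0_cols) < 2) return(sig)
  sigma <- stats::median(apply(sig[, b0_cols, drop = FALSE], 1, sd))
  if (!is.finite(sigma) || sigma <= 0) return(sig)
  sqrt(pmax(sig^2 - 2 * sigma^2, 0))
}

## Build the shared per-dataset matrices: forward operator rows for the
## b = 0 set + outermost shell, the isotropic columns, and the constraint
## basis. Shared across voxels (and subjects with a common protocol).
ss3t_matrices <- function(gtab, responses, options) {
  lmax <- options$lmax
  rows <- ss_rows(gtab)
  used <- c(rows$b0, rows$shell)
  ncoef <- sh_ncoef(lmax)
  n_zonal_have <- ncol(responses$wm)
  if (lmax / 2 + 1 > n_zonal_have)
    stop_invalid("response lmax (", responses$lmax,
                 ") lower than requested FOD lmax (", lmax, ")")

  shell_index <- function(b) which.min(abs(responses$shell_bvals - b))
  k0 <- shell_index(0)
  ks <- shell_index(rows$outer_b)

  zon <- function(k) responses$wm[k, seq_len(lmax / 2 + 1)]
  A_wm <- matrix(0, length(used), ncoef)
  # b = 0 rows: the kernel is isotropic, only l = 0 contributes
  r0 <- rh_factors(zon(k0), lmax)
  A_wm[seq_along(rows$b0), ] <-
    matrix(sh_basis(rbind(c(0, 0, 1)), lmax)$matrix, length(rows$b0), ncoef,
           byrow = TRUE) * matrix(r0, length(rows$b0), ncoef, byrow = TRUE)
  rs <- rh_factors(zon(ks), lmax)
  Bs <- sh_basis(gtab$bvecs[rows$shell, , drop = FALSE], lmax)$matrix
  A_wm[length(rows$b0) + seq_along(rows$shell), ] <-
    Bs * matrix(rs, length(rows$shell), ncoef, byrow = TRUE)

  col_iso <- function(resp) {
    v <- c(rep(resp[k0], length(rows$b0)), rep(resp[ks], length(rows$shell)))
    v / resp[k0] # normalized: weight is the b0-signal contribution
  }
  if (nrow(Bs) < ncoef || qr(Bs)$rank < ncoef)
    stop_invalid("rank-deficient forward operator: too few unique shell ",
                 "directions (", length(rows$shell), ") for lmax ", lmax)

  Bcon <- sh_basis(sphere_directions(options$n_constraint), lmax)$matrix

  # response-derived single-fiber FOD template: the non-negative
  # (apodized-delta) FOD whose convolution best reproduces the WM kernel
  s_kernel <- c(rep(responses$b0[["wm"]], length(rows$b0)),
                drop(Bs[, zonal_indices(lmax), drop = FALSE] %*% zon(ks)))
  peak_dirs <- sphere_directions(1000)
  Bpeak <- sh_basis(peak_dirs, lmax)$matrix
  # the dense grid keeps between-constraint dips of the template FOD
  # within the stated amplitude tolerance
  fpure <- cpp_solve_lsi(A_wm, s_kernel, Bpeak)
  template_zonal <- fpure[zonal_indices(lmax)]
  list(used_rows = used, A_wm = A_wm,
       col_gm = col_iso(responses$gm), col_csf = col_iso(responses$csf),
       Bcon = Bcon, wm_b0 = unname(responses$b0["wm"]), lmax = lmax,
       template_zonal = template_zonal, Bpeak = Bpeak,
       peak_dirs = peak_dirs, shell_zonal = zon(ks),
       shell_dirs = gtab$bvecs[rows$shell, , drop = FALSE],
       n_b0 = length(rows$b0))
}

#' Fit SS3T-CSD in a single voxel
#'
#' @param signal numeric vector, one value per gradient-table entry.
#' @param gtab [gradient_table()].
#' @param responses [estimate_responses()] result.
#' @param options [ss3t_options()].
#' @return list with `fod` (even SH coefficients), `weights` named
#'   `(w_ICA, w_ICI, w_ECI)` in b0-signal units, and `fractions`
#'   `(f_ECI, f_ICI, f_ICA)`.
#' @export
fit_ss3t <- function(signal, gtab, responses, options = ss3t_options()) {
  if (!length(ss_rows(gtab)$b0))
    stop_invalid("gradient table has no b = 0 measurements")
  mats <- ss3t_matrices(gtab, responses, options)
  sig <- matrix(signal[mats$used_rows], nrow = 1)
  if (isTRUE(options$rician_correction))
    sig <- rician_correct(sig, seq_along(ss_rows(gtab)$b0))
  fit <- cpp_fit_ss3t(sig,
                      mats$A_wm, mats$col_gm, mats$col_csf, mats$Bcon,
                      mats$wm_b0, options$eps, options$max_iter,
                      options$f00_ridge, mats$template_zonal, mats$Bpeak,
                      mats$peak_dirs, mats$shell_zonal, mats$shell_dirs,
                      mats$n_b0)
  w <- c(w_ICA = fit$w[1, 1], w_ICI = fit$w[1, 2], w_ECI = fit$w[1, 3])
  list(fod = drop(fit$fod), weights = w,
       fractions = drop(signal_fractions(rbind(unname(w)))))
}

#' Fit SS3T-CSD over all in-mask voxels of a dataset
#'
#' @param dwi `dwi_dataset`.
#' @param responses [estimate_responses()] result.
#' @param mask logical 3-D array (default the dataset brain mask).
#' @param options [ss3t_options()].
#' @return list with `fod` (class `fod_field`: 4-D coefficient array,
#'   `affine`, `lmax`, `mask`) and `fractions` (class `fraction_field`:
#'   4-D array ordered (f_ECI, f_ICI, f_ICA), NA outside the mask).
#' @export
fit_ss3t_field <- function(dwi, responses, mask = NULL,
                           options = ss3t_options()) {
  mask <- mask %||% dwi$brain_mask
  dims <- dim(dwi$data)[1:3]
  stopifnot(all(dim(mask) == dims))
  mats <- ss3t_matrices(dwi$gtab, responses, options)
  idx <- which(as.vector(mask))
  sig <- matrix(dwi$data, prod(dims), dim(dwi$data)[4])[idx, mats$used_rows,
                                                        drop = FALSE]
  if (isTRUE(options$rician_correction))
    sig <- rician_correct(sig, seq_along(ss_rows(dwi$gtab)$b0))
  fit <- cpp_fit_ss3t(sig, mats$A_wm, mats$col_gm, mats$col_csf, mats$Bcon,
                      mats$wm_b0, options$eps, options$max_iter,
                      options$f00_ridge, mats$template_zonal, mats$Bpeak,
                      mats$peak_dirs, mats$shell_zonal, mats$shell_dirs,
                      mats$n_b0)
  ncoef <- sh_ncoef(options$lmax)
  coef <- matrix(0, prod(dims), ncoef)
  coef[idx, ] <- fit$fod
  w <- matrix(NA_real_, prod(dims), 3)
  w[idx, ] <- fit$w
  fr <- signal_fractions(fit$w)
  frac <- matrix(NA_real_, prod(dims), 3)
  frac[idx, ] <- fr
  list(fod = structure(list(coef = array(coef, c(dims, ncoef)),
                            affine = dwi$affine, lmax = options$lmax,
                            mask = mask), class = "fod_field"),
       fractions = structure(list(f = array(frac, c(dims, 3)),
                                  affine = dwi$affine, mask = mask),
                             class = "fraction_field"))
}

#' Convert compartment weights to signal fractions
#'
#' `f_t = w_t / (w_ICA + w_ICI + w_ECI)`. All-zero (background) voxels map
#' to `NA` and are excluded from downstream statistics.
#'
#' @param weights n x 3 matrix ordered `(w_ICA, w_ICI, w_ECI)`,
#'   non-negative.
#' @return n x 3 matrix ordered `(f_ECI, f_ICI, f_ICA)`.
#' @export
signal_fractions <- function(weights) {
  weights <- rbind(weights)
  if (any(weights < 0, na.rm = TRUE))
    stop_invalid("negative compartment weight")
  tot <- rowSums(weights)
  out <- cbind(weights[, 3] / tot, weights[, 2] / tot, weights[, 1] / tot)
  out[tot == 0 | !is.finite(tot), ] <- NA_real_
  colnames(out) <- c("f_ECI", "f_ICI", "f_ICA")
  out
}

#' Direction of the largest FOD peak in one voxel
#'
#' Dense-grid argmax refined by a local quadratic step; adequate for
#' orientation-recovery checks.
#'
#' @param fod even SH coefficient vector.
#' @param n_dirs size of the search grid.
#' @return unit 3-vector.
#' @export
fod_peak <- function(fod, n_dirs = 2000) {
  dirs <- sphere_directions(n_dirs)
  amp <- fod_amplitude(fod, dirs, clip = FALSE)
  dirs[which.max(amp), ]
}
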