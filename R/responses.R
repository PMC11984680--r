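## Tissue response function estimation. The white-matter response is the
## per-shell zonal (m = 0) SH expansion of the signal in single-fiber voxels
## after reorienting each voxel's principal axis to +z; GM-like and
## CSF-like responses are per-shell mean signals. All three record their
## b = 0 amplitude.

#' Estimate WM/GM/CSF response functions from a DWI dataset
#'
#' @param dwi `dwi_dataset` (see [build_phantom()] or [read_dwi()]).
#' @param tissue_masks list with logical 3-D arrays `wm` (single-fiber white
#'   matter), `gm` and `csf`; each must be non-empty.
#' @param lmax even harmonic order of the WM zonal fit (default 8).
#' @param max_wm_voxels cap on the number of single-fiber voxels averaged
#'   into the WM response (a deterministic subset; 50 is ample for a
#'   stable zonal fit).
#' @return object of class `response_set`: list with `shell_bvals` (b = 0
#'   first), `wm` matrix (shells x zonal coefficients), `gm`, `csf` per-shell
#'   mean-signal vectors, and `b0` amplitudes per tissue.
#' @export
estimate_responses <- function(dwi, tissue_masks, lmax = 8,
                               max_wm_voxels = 50) {
  for (t in c("wm", "gm", "csf"))
    if (!any(tissue_masks[[t]]))
      stop("missing tissue: empty ", t, " mask in estimate_responses")
  gtab <- dwi$gtab
  nmeas <- length(gtab$bvals)
  dims <- dim(dwi$data)[1:3]
  sig <- matrix(dwi$data, prod(dims), nmeas)

  shell_b <- c(0, gtab$shell_bvals)
  rows_of <- lapply(seq_along(shell_b), function(k)
    which(gtab$shell_of == (k - 1L)))

  iso_resp <- function(mask) {
    s <- sig[as.vector(mask), , drop = FALSE]
    vapply(rows_of, function(r) mean(s[, r]), 0)
  }
  gm <- iso_resp(tissue_masks$gm)
  csf <- iso_resp(tissue_masks$csf)

  wm_vox <- which(as.vector(tissue_masks$wm))
  if (length(wm_vox) > max_wm_voxels)
    wm_vox <- wm_vox[round(seq(1, length(wm_vox), length.out = max_wm_voxels))]
  n_zonal <- lmax / 2 + 1
  acc <- matrix(0, length(shell_b), n_zonal)
  for (v in wm_vox) {
    s <- sig[v, ]
    dirv <- principal_axis(s, gtab)
    R <- rotation_to_z(dirv)
    for (k in seq_along(shell_b)) {
      r <- rows_of[[k]]
      if (k == 1) { # b = 0: isotropic, Z_0 = mean * sqrt(4 pi)
        acc[1, 1] <- acc[1, 1] + mean(s[r]) * sqrt(4 * pi)
        next
      }
      g <- gtab$bvecs[r, , drop = FALSE] %*% t(R)
      Bz <- sh_basis(g, lmax)$matrix[, zonal_indices(lmax), drop = FALSE]
      acc[k, ] <- acc[k, ] + qr.solve(Bz, s[r])
    }
  }
  wm <- acc / length(wm_vox)
  structure(list(shell_bvals = shell_b, lmax = lmax, wm = wm,
                 gm = gm, csf = csf,
                 b0 = c(wm = wm[1, 1] / sqrt(4 * pi), gm = gm[1],
                        csf = csf[1])),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat("response_set: shells b =", paste(round(x$shell_bvals), collapse = ", "),
      "; WM lmax", x$lmax, "; b0 amplitudes",
      paste(sprintf("%s=%.3f", names(x$b0), x$b0), collapse = " "), "\n")
  invisible(x)
}

## principal diffusion axis of one voxel via a log-linear tensor fit
principal_axis <- function(s, gtab) {
  nz <- which(gtab$bvals > 0)
  g <- gtab$bvecs[nz, , drop = FALSE]
  b <- gtab$bvals[nz]
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  y <- log(pmax(s[nz], 1e-8))
  beta <- qr.solve(X, y)
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  e$vectors[, 1]
}

## rotation matrix R with R v = z (Rodrigues)
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s_ <- sqrt(sum(axis^2))
  axis <- axis / s_
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * K %*% K
}

## analytic zonal coefficients of the zeppelin kernel at b (oracle + fast
## path for building forward matrices from known diffusivities)
zeppelin_zonal <- function(b, d_ax, d_rad, lmax) {
  n_zonal <- lmax / 2 + 1
  out <- numeric(n_zonal)
  for (i in seq_len(n_zonal)) {
    l <- 2 * (i - 1)
    f <- function(ct) {
      # evaluate Y_l0(theta) via the basis at (sin t, 0, cos t)
      dirs <- cbind(sqrt(pmax(0, 1 - ct^2)), 0, ct)
      amp <- sh_basis(dirs, lmax)$matrix[, zonal_indices(lmax)[i]]
      exp(-b * (d_rad + (d_ax - d_rad) * ct^2)) * amp
    }
    out[i] <- 2 * pi * integrate(f, -1, 1, rel.tol = 1e-10)$value
  }
  out
}
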