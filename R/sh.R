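## Real even-order spherical harmonic (SH) machinery used by the CSD and
## tractography stages. Convention (matching the MRtrix real basis):
##   m = 0 : Y_lm = K(l,0) P_l^0(cos theta)
##   m > 0 : Y_lm = sqrt(2) K(l,m) P_l^m(cos theta) cos(m phi)
##   m < 0 : Y_lm = sqrt(2) K(l,|m|) P_l^|m|(cos theta) sin(|m| phi)
## with K(l,m) = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and Condon-Shortley phase
## inside P_l^m. Only even l are kept (diffusion signal is antipodally
## symmetric), coefficients ordered l = 0, 2, ..., lmax with m = -l..l.

#' Number of even-order real SH coefficients up to `lmax`
#' @param lmax even non-negative integer.
#' @return integer, `(lmax + 1) * (lmax + 2) / 2`.
#' @export
sh_ncoef <- function(lmax) (lmax + 1L) * (lmax + 2L) / 2L

#' (l, m) index table for the even real SH basis
#' @param lmax even non-negative integer.
#' @return data.frame with columns `l` and `m`, one row per coefficient.
#' @export
sh_lm <- function(lmax) {
  l <- unlist(lapply(seq(0L, lmax, by = 2L), function(li) rep(li, 2L * li + 1L)))
  m <- unlist(lapply(seq(0L, lmax, by = 2L), function(li) seq(-li, li)))
  data.frame(l = l, m = m)
}

## associated Legendre P_l^m(x) (Condon-Shortley) for all 0 <= m <= l <= lmax;
## returns a list indexed [[l + 1]][[m + 1]] of vectors along x
legendre_table <- function(lmax, x) {
  p <- vector("list", lmax + 1L)
  for (l in 0:lmax) p[[l + 1L]] <- vector("list", l + 1L)
  p[[1L]][[1L]] <- rep(1, length(x))
  if (lmax >= 1) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    for (m in 1:lmax) {
      # P_mm = (-1)^m (2m-1)!! (1-x^2)^(m/2)
      p[[m + 1L]][[m + 1L]] <- p[[m]][[m]] * (-(2 * m - 1)) * somx2
    }
    for (m in 0:(lmax - 1)) {
      p[[m + 2L]][[m + 1L]] <- x * (2 * m + 1) * p[[m + 1L]][[m + 1L]]
      if (m + 2 <= lmax) {
        for (l in (m + 2):lmax) {
          p[[l + 1L]][[m + 1L]] <-
            ((2 * l - 1) * x * p[[l]][[m + 1L]] -
               (l + m - 1) * p[[l - 1L]][[m + 1L]]) / (l - m)
        }
      }
    }
  }
  p
}

#' Evaluate the real even SH basis at a set of directions
#'
#' @param directions n x 3 matrix of unit vectors (need not be normalized;
#'   they are normalized internally, zero rows are rejected).
#' @param lmax even non-negative integer; the maximum harmonic order.
#' @return an object of class `sh_basis`: list with `lmax`, `directions` and
#'   the n x `sh_ncoef(lmax)` design `matrix`.
#' @export
sh_basis <- function(directions, lmax) {
  if (length(lmax) != 1 || lmax < 0 || lmax %% 2 != 0)
    stop_invalid("lmax must be a single even non-negative integer, got ", lmax)
  directions <- rbind(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-12)) stop_invalid("zero direction vector in sh_basis")
  directions <- directions / nrm
  x <- directions[, 3]                      # cos(theta)
  phi <- atan2(directions[, 2], directions[, 1])
  tab <- legendre_table(lmax, x)
  idx <- sh_lm(lmax)
  B <- matrix(0, nrow(directions), nrow(idx))
  for (j in seq_len(nrow(idx))) {
    l <- idx$l[j]; m <- idx$m[j]; am <- abs(m)
    k <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    p <- tab[[l + 1L]][[am + 1L]]
    B[, j] <- if (m == 0) k * p
              else if (m > 0) sqrt(2) * k * p * cos(m * phi)
              else sqrt(2) * k * p * sin(am * phi)
  }
  structure(list(lmax = lmax, directions = directions, matrix = B),
            class = "sh_basis")
}

#' Evaluate FOD amplitudes along directions
#'
#' @param fod numeric vector of even SH coefficients (one voxel).
#' @param directions n x 3 unit vectors, or an `sh_basis` object.
#' @param clip clip amplitudes at zero (default TRUE; used when sampling).
#' @return numeric vector of amplitudes.
#' @export
fod_amplitude <- function(fod, directions, clip = TRUE) {
  basis <- if (inherits(directions, "sh_basis")) directions
           else sh_basis(directions, lmax_from_ncoef(length(fod)))
  amp <- drop(basis$matrix %*% fod)
  if (clip) pmax(amp, 0) else amp
}

lmax_from_ncoef <- function(n) {
  lmax <- (-3 + sqrt(1 + 8 * n)) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop_invalid("coefficient count ", n, " does not match an even lmax")
  as.integer(round(lmax))
}

#' Deterministic quasi-uniform directions on the sphere (Fibonacci lattice)
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## zonal (m = 0) column indices within the even basis
zonal_indices <- function(lmax) which(sh_lm(lmax)$m == 0)

## rotational-harmonic convolution factors: multiply FOD coefficients of
## order l by sqrt(4 pi / (2 l + 1)) * Z_l, Z_l the kernel zonal coefficients
rh_factors <- function(zonal, lmax) {
  idx <- sh_lm(lmax)
  lset <- seq(0L, lmax, by = 2L)
  f <- sqrt(4 * pi / (2 * lset + 1)) * zonal
  f[match(idx$l, lset)]
}
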