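## Gradient tables for multi-shell diffusion acquisitions.

#' Build a multi-shell gradient table
#'
#' Produces `n_b0` b = 0 entries plus, for each shell b-value,
#' `n_dirs_per_shell` approximately uniform unit vectors laid out by
#' electrostatic repulsion on the projective sphere (antipodal pairs treated
#' as identical), with hemisphere signs chosen so the direction set is
#' balanced (mean vector near zero). The layout is deterministic given the
#' inputs; no random number generation is used.
#'
#' @param n_b0 number of b = 0 measurements.
#' @param n_dirs_per_shell number of gradient directions per shell (>= 6).
#' @param shell_bvals distinct positive b-values, s/mm^2.
#' @return object of class `gradient_table`: list with `bvals` (length n),
#'   `bvecs` (n x 3; zero rows for b = 0), `shell_of` (0 for b = 0, else
#'   shell index) and `shell_bvals`.
#' @export
make_gradient_table <- function(n_b0, n_dirs_per_shell, shell_bvals) {
  if (any(shell_bvals <= 0))
    stop_invalid("shell b-values must be positive, got ",
                 paste(shell_bvals, collapse = ", "))
  if (anyDuplicated(shell_bvals))
    stop_invalid("shell b-values must be distinct")
  if (n_dirs_per_shell < 6)
    stop_invalid("need at least 6 directions per shell")
  # the repulsion layout is deterministic in n; memoize it
  key <- paste0("dirs", n_dirs_per_shell)
  dirs <- .lesionometry_cache[[key]]
  if (is.null(dirs)) {
    dirs <- repulsion_directions(n_dirs_per_shell)
    .lesionometry_cache[[key]] <- dirs
  }
  bvals <- c(rep(0, n_b0), rep(shell_bvals, each = n_dirs_per_shell))
  bvecs <- rbind(matrix(0, n_b0, 3),
                 do.call(rbind, rep(list(dirs), length(shell_bvals))))
  gradient_table(bvals, bvecs)
}

#' Construct a gradient table from raw bvals/bvecs
#'
#' Shells are identified by clustering b-values within +/- 50 s/mm^2.
#'
#' @param bvals numeric vector of non-negative b-values.
#' @param bvecs n x 3 matrix; non-zero rows must be unit vectors.
#' @return `gradient_table` object.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != nrow(bvecs))
    stop("format error: bvals and bvecs lengths differ (",
         length(bvals), " vs ", nrow(bvecs), ")")
  if (any(bvals < 0)) stop_invalid("negative b-value")
  nrm <- sqrt(rowSums(bvecs^2))
  nz <- bvals > 0
  if (any(abs(nrm[nz] - 1) > 1e-6)) {
    if (any(nrm[nz] < 1e-6))
      stop("format error: zero gradient vector on a non-zero shell")
    bvecs[nz, ] <- bvecs[nz, ] / nrm[nz]
  }
  bvecs[!nz, ] <- 0
  shells <- cluster_shells(bvals[nz])
  shell_of <- integer(length(bvals))
  shell_of[nz] <- shells$id
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 shell_of = shell_of, shell_bvals = shells$centers),
            class = "gradient_table")
}

cluster_shells <- function(b, tol = 50) {
  if (!length(b)) return(list(id = integer(0), centers = numeric(0)))
  o <- order(b)
  id <- integer(length(b))
  centers <- numeric(0)
  for (i in o) {
    hit <- which(abs(centers - b[i]) <= tol)
    if (length(hit)) {
      id[i] <- hit[1]
    } else {
      centers <- c(centers, b[i])
      id[i] <- length(centers)
    }
  }
  # refine centers to cluster means
  for (k in seq_along(centers)) centers[k] <- mean(b[id == k])
  list(id = id, centers = centers)
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("gradient_table:", length(x$bvals), "entries,",
      sum(x$bvals == 0), "b=0,", length(x$shell_bvals), "shell(s) at b =",
      paste(round(x$shell_bvals), collapse = ", "), "s/mm^2\n")
  invisible(x)
}

## deterministic electrostatic-repulsion layout on the projective sphere,
## followed by greedy sign balancing so the emitted set has near-zero mean
repulsion_directions <- function(n, n_iter = 120, step = 0.005) {
  x <- sphere_directions(n)
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(x[-i, , drop = FALSE], 2, x[i, ], function(a, b) b - a)
      d2 <- sweep(x[-i, , drop = FALSE], 2, x[i, ], `+`)
      r1 <- pmax(rowSums(d1^2), 1e-8)^1.5
      r2 <- pmax(rowSums(d2^2), 1e-8)^1.5
      force[i, ] <- colSums(d1 / r1) + colSums(d2 / r2)
    }
    # project onto tangent plane, take a bounded step, renormalize
    force <- force - x * rowSums(force * x)
    fn <- sqrt(rowSums(force^2))
    force <- force / pmax(fn, 1) * pmin(fn, 1)
    x <- x + step * force
    x <- x / sqrt(rowSums(x^2))
  }
  # greedy sign assignment keeps the running vector sum small
  s <- c(0, 0, 0)
  for (i in seq_len(n)) {
    if (sum((s + x[i, ])^2) > sum((s - x[i, ])^2)) x[i, ] <- -x[i, ]
    s <- s + x[i, ]
  }
  x
}

## indices of the measurement rows used by single-shell CSD: all b = 0 rows
## plus the outermost shell
ss_rows <- function(gtab) {
  outer_id <- which.max(gtab$shell_bvals)
  list(b0 = which(gtab$shell_of == 0),
       shell = which(gtab$shell_of == outer_id),
       outer_b = gtab$shell_bvals[outer_id])
}
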