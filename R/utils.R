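#' @useDynLib lesionometry, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm pf pt qt rbinom rnorm runif sd integrate
#' @importFrom utils read.table write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## session cache for deterministic, input-independent objects
.lesionometry_cache <- new.env(parent = emptyenv())

stop_invalid <- function(...) {
  stop(structure(class = c("lesionometry_invalid_spec", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a reproducible sub-seed from a global seed and a string key
#'
#' A single global seed deterministically derives per-stage, per-subject
#' sub-seeds via an FNV-1a hash of `"<seed>/<key>"`, so subject-level
#' parallelism or reordering cannot change results. The result is always a
#' valid 31-bit non-negative integer seed.
#'
#' @param seed integer global seed.
#' @param ... character/numeric components identifying the stage or subject.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  bytes <- utf8ToInt(key)
  # FNV-1a, 32-bit, done in double arithmetic (exact below 2^53)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; exact in double arithmetic
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- (h * 16777619) %% 2^32
  }
  as.integer(h %% 2^31)
}

with_seed <- function(seed, code) {
  force(seed)  # evaluate any RNG use in the caller's promise first
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## affine helpers: the 4x4 affine maps continuous grid coordinates to world
## mm, with voxel i occupying the half-open box [i, i+1) in grid units
## (voxel centre at i + 0.5).

make_affine <- function(voxel_size, origin = c(0, 0, 0)) {
  a <- diag(4)
  a[1, 1] <- a[2, 2] <- a[3, 3] <- voxel_size
  a[1:3, 4] <- origin
  a
}

affine_equal <- function(a, b, tol = 1e-5) {
  is.matrix(a) && is.matrix(b) && all(dim(a) == c(4, 4)) &&
    all(dim(b) == c(4, 4)) && max(abs(a - b)) <= tol
}

check_affine_match <- function(a, b, what = "volumes") {
  if (!affine_equal(a, b))
    stop("alignment error: affines of paired ", what,
         " differ by more than 1e-5")
  invisible(TRUE)
}

grid_to_world <- function(affine, g) {
  g <- rbind(t(g), 1)
  t(affine %*% g)[, 1:3, drop = FALSE]
}

world_to_grid <- function(affine, p) {
  inv <- solve(affine)
  p <- rbind(t(p), 1)
  t(inv %*% p)[, 1:3, drop = FALSE]
}

voxel_volume <- function(affine) abs(det(affine[1:3, 1:3]))

## centres of all voxels, n x 3 world mm, in array index order
voxel_centers <- function(dims, affine) {
  g <- as.matrix(expand.grid(seq_len(dims[1]) - 0.5,
                             seq_len(dims[2]) - 0.5,
                             seq_len(dims[3]) - 0.5))
  colnames(g) <- NULL
  grid_to_world(affine, g)
}
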