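## Whole-volume probabilistic tractography on the FOD field. A first-order
## probabilistic sampler draws each step direction by rejection sampling
## proportional to the trilinearly interpolated FOD amplitude within a cone
## around the incoming direction; streamlines grow bidirectionally from
## uniformly seeded points, terminate on low amplitude / mask exit /
## maximum length, and are rejected if shorter than the minimum length.

#' Tractography parameters
#'
#' @param step_size step length, mm.
#' @param max_angle maximum angle per step, degrees (0 < angle < 90).
#' @param cutoff FOD amplitude below which propagation terminates.
#' @param min_length minimum accepted streamline length, mm (the published
#'   criterion is 2.6 mm).
#' @param max_length maximum streamline length, mm.
#' @param target_count number of accepted streamlines to generate.
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(step_size = 0.65, max_angle = 30, cutoff = 0.05,
                            min_length = 2.6, max_length = 250,
                            target_count = 20000) {
  if (min_length < 0) stop_invalid("min_length must be >= 0")
  if (max_angle <= 0 || max_angle >= 90)
    stop_invalid("max_angle must be in (0, 90) degrees")
  if (step_size <= 0) stop_invalid("step_size must be positive")
  structure(list(step_size = step_size, max_angle = max_angle,
                 cutoff = cutoff, min_length = min_length,
                 max_length = max_length, target_count = target_count),
            class = "tracking_params")
}

#' Draw seed points uniformly over the in-mask voxel volume
#'
#' Each seed picks a random in-mask voxel, then a uniform position within
#' that voxel's box; coordinates are world mm.
#'
#' @param mask logical 3-D array.
#' @param n number of seeds.
#' @param affine 4x4 grid-to-world affine.
#' @return n x 3 matrix of world coordinates.
#' @export
seed_points <- function(mask, n, affine) {
  idx <- which(mask)
  if (!length(idx)) stop("empty mask: no voxels to seed")
  dims <- dim(mask)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  ijk <- arrayInd(pick, dims) - 1L
  g <- ijk + matrix(runif(3 * n), n, 3)
  grid_to_world(affine, g)
}

new_tractogram <- function(streamlines, affine, seed_count, rng_seed,
                           step_size) {
  structure(list(streamlines = streamlines, affine = affine,
                 seed_count = seed_count, rng_seed = rng_seed,
                 step_size = step_size), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  len <- streamline_lengths(x)
  cat("tractogram:", length(x$streamlines), "streamlines,",
      x$seed_count, "seeds attempted; length",
      if (length(len)) paste0("[", round(min(len), 2), ", ",
                              round(max(len), 2), "] mm") else "-", "\n")
  invisible(x)
}

#' Streamline lengths in mm
#' @param tractogram a `tractogram`.
#' @return numeric vector.
#' @export
streamline_lengths <- function(tractogram) {
  vapply(tractogram$streamlines,
         function(p) (nrow(p) - 1) * tractogram$step_size, 0)
}

fod_field_inputs <- function(fod_field, mask = NULL) {
  mask <- mask %||% fod_field$mask
  dims <- dim(fod_field$coef)[1:3]
  list(coef = as.numeric(fod_field$coef), dims = as.integer(dims),
       ncoef = dim(fod_field$coef)[4],
       mask = as.integer(as.vector(mask)), affine = fod_field$affine)
}

#' Propagate a single streamline from a seed point
#'
#' @param fod_field `fod_field` from [fit_ss3t_field()].
#' @param seed length-3 world coordinate inside the mask.
#' @param params [tracking_params()].
#' @param seed_rng integer RNG seed.
#' @return n x 3 matrix of points, or NULL if the streamline was rejected
#'   (shorter than `min_length`).
#' @export
propagate_streamline <- function(fod_field, seed, params = tracking_params(),
                                 seed_rng = 1L) {
  fi <- fod_field_inputs(fod_field)
  d300 <- sphere_directions(300)
  B300 <- cpp_sh_eval(d300, fod_field$lmax)
  res <- with_seed(seed_rng,
    cpp_propagate_batch(fi$coef, fi$dims, fi$ncoef, fi$mask, fi$affine,
                        rbind(as.numeric(seed)), unclass(params), B300, d300))
  if (res$accepted[1]) res$streamlines[[1]] else NULL
}

#' Generate a whole-volume tractogram
#'
#' Repeats seeding and propagation until `target_count` streamlines pass the
#' length filter. Errors if the acceptance rate collapses (degenerate FOD
#' field).
#'
#' @param fod_field `fod_field`.
#' @param mask seeding/tracking mask (default the FOD field's mask).
#' @param params [tracking_params()].
#' @param seed integer RNG seed; fixed seed gives an identical tractogram.
#' @return a `tractogram`.
#' @export
generate_tractogram <- function(fod_field, mask = NULL,
                                params = tracking_params(), seed = 1L) {
  mask <- mask %||% fod_field$mask
  fi <- fod_field_inputs(fod_field, mask)
  d300 <- sphere_directions(300)
  B300 <- cpp_sh_eval(d300, fod_field$lmax)
  target <- params$target_count
  with_seed(seed, {
    keep <- vector("list", target)
    have <- 0L
    attempted <- 0L
    rate <- 0.25
    while (have < target) {
      chunk <- min(max(ceiling((target - have) / max(rate, 0.02)), 100L),
                   200000L)
      seeds <- seed_points(mask, chunk, fod_field$affine)
      res <- cpp_propagate_batch(fi$coef, fi$dims, fi$ncoef, fi$mask,
                                 fi$affine, seeds, unclass(params), B300,
                                 d300)
      attempted <- attempted + chunk
      acc <- which(res$accepted)
      if (length(acc)) {
        take <- acc[seq_len(min(length(acc), target - have))]
        keep[have + seq_along(take)] <- res$streamlines[take]
        have <- have + length(take)
      }
      rate <- (have + 1) / (attempted + 1)
      if (attempted >= 10 * target && rate < 1e-4)
        stop("degenerate FOD field: streamline acceptance rate ",
             signif(rate, 2), " after ", attempted, " seeds")
    }
    new_tractogram(keep, fod_field$affine, attempted, seed,
                   params$step_size)
  })
}

## concatenate streamline points for the C++ traversal
flatten_streamlines <- function(tractogram) {
  ns <- vapply(tractogram$streamlines, nrow, 0L)
  list(coords = do.call(rbind, tractogram$streamlines),
       offsets = as.integer(c(0, cumsum(ns))))
}

#' Per-streamline visited voxels (exact segment traversal)
#'
#' @param tractogram a `tractogram`.
#' @param dims grid dimensions.
#' @param affine grid-to-world affine of the target grid.
#' @return list of integer vectors of 1-based linear voxel indices, one per
#'   streamline, each voxel counted once per streamline.
#' @export
streamline_voxels <- function(tractogram, dims,
                              affine = tractogram$affine) {
  if (!length(tractogram$streamlines)) return(list())
  fl <- flatten_streamlines(tractogram)
  lst <- cpp_streamline_voxels(fl$coords, fl$offsets, affine,
                               as.integer(dims))
  lapply(lst, function(v) v + 1L)
}

#' Track-density map
#'
#' `TD(v)` = number of distinct streamlines whose polyline intersects voxel
#' `v` (each streamline counted once per voxel), by exact segment-voxel
#' traversal.
#'
#' @param tractogram a `tractogram`.
#' @param dims grid dimensions.
#' @param affine grid-to-world affine (defaults to the tractogram's).
#' @return integer 3-D array.
#' @export
track_density_map <- function(tractogram, dims,
                              affine = tractogram$affine) {
  vox <- streamline_voxels(tractogram, dims, affine)
  td <- tabulate(unlist(vox), nbins = prod(dims))
  array(as.integer(td), dims)
}

#' SIFT-style tractogram pruning
#'
#' Greedy removal tying streamline density to FOD magnitude: with
#' `TD(v)` the streamline visitation count and `A(v)` the FOD l = 0 (mean)
#' amplitude, repeatedly deletes the streamline whose removal most
#' decreases `sum_v (mu TD(v) - A(v))^2`, refitting the density-matching
#' scale `mu` after each batch, until `keep_count` streamlines remain.
#'
#' @param tractogram a `tractogram`.
#' @param fod_field `fod_field` on the same grid.
#' @param keep_count number of streamlines to retain (> 0, <= input count).
#' @param batch refit `mu` after this many removals (default 1: refit
#'   after every removal, which keeps the cost monotone through deep
#'   pruning).
#' @return the pruned `tractogram`, with attributes `sift_cost` (cost after
#'   each removal, non-increasing) and `sift_mu`.
#' @export
sift_filter <- function(tractogram, fod_field, keep_count, batch = 1) {
  n <- length(tractogram$streamlines)
  if (keep_count <= 0) stop_invalid("keep_count must be positive")
  if (keep_count > n)
    stop_invalid("keep_count (", keep_count, ") exceeds streamline count (",
                 n, ")")
  check_affine_match(tractogram$affine, fod_field$affine, "tractogram/FOD")
  if (keep_count == n) return(tractogram)
  dims <- dim(fod_field$coef)[1:3]
  vox0 <- streamline_voxels(tractogram, dims)
  amp <- as.numeric(fod_field$coef[, , , 1]) / sqrt(4 * pi) # mean amplitude
  res <- cpp_sift(lapply(vox0, function(v) v - 1L), amp,
                  as.integer(keep_count), as.integer(batch))
  out <- tractogram
  out$streamlines <- tractogram$streamlines[res$kept]
  attr(out, "sift_cost") <- res$cost
  attr(out, "sift_mu") <- res$mu
  out
}
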