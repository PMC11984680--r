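## Shared fixtures, memoized per test run. Everything is generated in code;
## no stored binary data.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

two_shell_gtab <- function() memo("gtab", make_gradient_table(10, 64, c(1500, 3000)))

## 8^3 phantom with a straight z bundle, GM background, CSF corner
small_phantom <- function() memo("small_phantom", {
  spec <- phantom_spec(grid_shape = c(8, 8, 8), voxel_size = 1.7,
                       bundles = list(bundle_spec(rbind(c(6.8, 6.8, 0),
                                                        c(6.8, 6.8, 13.6)),
                                                  radius_mm = 3)),
                       csf_corner_mm = 3.5)
  build_phantom(spec, two_shell_gtab())
})

small_responses <- function() memo("small_responses", {
  ph <- small_phantom()
  estimate_responses(ph$dwi, ph$truth$tissue_masks)
})

## default 20^3 bundle phantom fitted at lmax 8 (used by several criteria)
default_fit <- function() memo("default_fit", {
  ph <- build_phantom(default_phantom_spec())
  resp <- estimate_responses(ph$dwi, ph$truth$tissue_masks)
  c(ph, list(responses = resp,
             fit = fit_ss3t_field(ph$dwi, resp)))
})

## fit many single-voxel signals through one shared operator (fast path)
fit_voxels <- function(signals, gtab, responses, lmax = 8) {
  n <- nrow(signals)
  dwi <- structure(list(data = array(signals, c(n, 1, 1, ncol(signals))),
                        gtab = gtab, affine = diag(4),
                        brain_mask = array(TRUE, c(n, 1, 1))),
                   class = "dwi_dataset")
  fit_ss3t_field(dwi, responses, options = ss3t_options(lmax = lmax))
}

## toy hand-built tractogram: list of n x 3 point matrices in world mm
toy_tractogram <- function(streamlines, affine = diag(4), step = NA_real_) {
  lesionometry:::new_tractogram(streamlines, affine, length(streamlines),
                                0L, step)
}

## brute-force dense-sampling membership oracle for segment traversal
## (>= 100x oversampled: n_per_segment points per segment)
oracle_streamline_voxels <- function(streamlines, dims, affine,
                                     n_per_segment = 1000) {
  lapply(streamlines, function(p) {
    pts <- do.call(rbind, lapply(seq_len(nrow(p) - 1), function(k)
      outer(seq(0, 1, length.out = n_per_segment), p[k + 1, ] - p[k, ]) +
        matrix(p[k, ], n_per_segment, 3, byrow = TRUE)))
    if (is.null(pts)) pts <- p
    g <- floor(lesionometry:::world_to_grid(affine, pts))
    ok <- g[, 1] >= 0 & g[, 2] >= 0 & g[, 3] >= 0 &
      g[, 1] < dims[1] & g[, 2] < dims[2] & g[, 3] < dims[3]
    sort(unique(as.integer(g[ok, 1] + dims[1] * (g[ok, 2] +
                                                   dims[2] * g[ok, 3]) + 1)))
  })
}

## straight axis-aligned streamline through given voxel centres (world mm)
line_through <- function(from_mm, to_mm, n = 12) {
  t(sapply(seq(0, 1, length.out = n), function(a) from_mm + a * (to_mm - from_mm)))
}
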