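## Synthetic diffusion phantom: a gridded multi-shell acquisition over fiber
## bundles, GM-like and CSF-like regions, and spherical WMH lesions, with
## exact ground truth. The forward model is a three-compartment mixture:
## an axially symmetric "zeppelin" tensor for the intracellular anisotropic
## (ICA) compartment and monoexponential isotropic decay for the
## intracellular isotropic (ICI, GM-like) and extracellular isotropic
## (ECI, CSF-like free water) compartments. Fraction triples are always
## ordered (f_ECI, f_ICI, f_ICA) and sum to 1.

default_diffusivities <- function() {
  list(d_csf = 3.0e-3, d_gm = 0.8e-3, d_ax = 1.7e-3, d_rad = 0.2e-3)
}

#' Specify a fiber bundle for the phantom
#'
#' @param centerline k x 3 matrix of control points in world mm; consecutive
#'   points are joined by straight segments.
#' @param radius_mm bundle radius in mm.
#' @param fractions `(f_ECI, f_ICI, f_ICA)` inside the bundle; default a pure
#'   axonal compartment.
#' @return `bundle_spec` list.
#' @export
bundle_spec <- function(centerline, radius_mm, fractions = c(0, 0, 1)) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3, nrow(centerline) >= 2, radius_mm > 0)
  check_fractions(fractions)
  structure(list(centerline = centerline, radius_mm = radius_mm,
                 fractions = fractions), class = "bundle_spec")
}

#' Specify a spherical WMH lesion
#'
#' Voxels whose centre lies within `radius_mm` of `center_mm` take the
#' lesion fraction triple (elevated free water / intracellular isotropic
#' signal, reduced axonal signal). An optional penumbra shifts signal from
#' the axonal to the free-water compartment in bundle voxels within
#' `penumbra_mm` beyond the lesion boundary, emulating Wallerian
#' degeneration along lesioned tracts.
#'
#' @param center_mm length-3 world coordinate of the lesion centre.
#' @param radius_mm lesion radius, mm.
#' @param fractions `(f_ECI, f_ICI, f_ICA)` inside the lesion.
#' @param penumbra_mm width of the peri-lesional damaged rim (0 = none).
#' @param penumbra_delta_eci amount of signal fraction moved from ICA to ECI
#'   in penumbra voxels that carry axonal signal.
#' @return `lesion_spec` list.
#' @export
lesion_spec <- function(center_mm, radius_mm,
                        fractions = c(0.55, 0.30, 0.15),
                        penumbra_mm = 0, penumbra_delta_eci = 0) {
  stopifnot(length(center_mm) == 3, radius_mm > 0, penumbra_mm >= 0)
  check_fractions(fractions)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 fractions = fractions, penumbra_mm = penumbra_mm,
                 penumbra_delta_eci = penumbra_delta_eci),
            class = "lesion_spec")
}

check_fractions <- function(f) {
  if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop_invalid("fraction triple must be non-negative and sum to 1, got (",
                 paste(format(f), collapse = ", "), ")")
  invisible(f)
}

#' Specify a synthetic diffusion phantom
#'
#' @param grid_shape three positive integers, grid dimensions.
#' @param voxel_size isotropic voxel size, mm.
#' @param bundles list of [bundle_spec()] objects.
#' @param background `(f_ECI, f_ICI, f_ICA)` for non-bundle voxels
#'   (GM-like by default; must have `f_ICA = 0`, background carries no
#'   orientation).
#' @param csf_corner_mm if positive, voxels within this distance (mm, along
#'   every axis) of the grid origin corner form a CSF-like block
#'   (`fractions = (1, 0, 0)`), used for response estimation.
#' @param lesions list of [lesion_spec()] objects; spheres must lie inside
#'   the grid.
#' @param diffusivities list with `d_csf`, `d_gm`, `d_ax`, `d_rad` in mm^2/s.
#' @param snr signal-to-noise ratio on the b = 0 signal (`Inf` = noiseless);
#'   noise is Rician (magnitude of complex Gaussian).
#' @param mask_margin_mm if non-NULL, restrict the brain mask to voxels
#'   within this distance of a bundle centerline or lesion centre (keeps
#'   desk-scale cohort runs cheap); otherwise the mask covers the full grid.
#' @param seed integer RNG seed for the noise draw.
#' @return `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(20, 20, 20), voxel_size = 1.7,
                         bundles = list(), background = c(0.1, 0.9, 0),
                         csf_corner_mm = 0, lesions = list(),
                         diffusivities = default_diffusivities(),
                         snr = Inf, mask_margin_mm = NULL, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size > 0)
  check_fractions(background)
  if (!is.infinite(snr) && snr <= 0) stop_invalid("snr must be positive")
  for (b in bundles) stopifnot(inherits(b, "bundle_spec"))
  ext <- grid_shape * voxel_size
  for (l in lesions) {
    stopifnot(inherits(l, "lesion_spec"))
    if (any(l$center_mm - l$radius_mm < 0) ||
        any(l$center_mm + l$radius_mm > ext))
      stop_invalid("lesion sphere extends outside the grid")
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 bundles = bundles, background = background,
                 csf_corner_mm = csf_corner_mm, lesions = lesions,
                 diffusivities = diffusivities, snr = snr,
                 mask_margin_mm = mask_margin_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default straight-bundle phantom
#'
#' A 20 x 20 x 20 grid at 1.7 mm isotropic containing a straight z-axis
#' bundle of pure axonal tissue, GM-like background, a CSF-like corner
#' block, and one spherical WMH lesion strictly interior to the bundle.
#'
#' @param snr signal-to-noise ratio (default noiseless).
#' @param seed RNG seed for the noise draw.
#' @return `phantom_spec`.
#' @export
default_phantom_spec <- function(snr = Inf, seed = 1L) {
  vs <- 1.7; n <- 20; c_xy <- n * vs / 2
  phantom_spec(
    grid_shape = c(n, n, n), voxel_size = vs,
    bundles = list(bundle_spec(rbind(c(c_xy, c_xy, 0), c(c_xy, c_xy, n * vs)),
                               radius_mm = 4)),
    csf_corner_mm = 3.5,
    lesions = list(lesion_spec(c(c_xy, c_xy, n * vs / 2), radius_mm = 3.4)),
    snr = snr, seed = seed)
}

#' Simulate the diffusion signal of one voxel
#'
#' `S(b, g) = f_ICA exp(-b [ (d_ax - d_rad)(g.v)^2 + d_rad ]) +
#'  f_ICI exp(-b d_gm) + f_ECI exp(-b d_csf)`, scaled so `S(0) = 1`, with
#' Rician noise at the given SNR (none when `snr = Inf`).
#'
#' @param gtab [gradient_table()].
#' @param fractions `(f_ECI, f_ICI, f_ICA)`, summing to 1.
#' @param fiber_dir unit 3-vector, required when `f_ICA > 0`.
#' @param diffusivities list with `d_csf`, `d_gm`, `d_ax`, `d_rad`.
#' @param snr b0 SNR (Rician); `Inf` for noiseless.
#' @return numeric vector, one signal per gradient-table entry.
#' @export
simulate_voxel_signal <- function(gtab, fractions, fiber_dir = NULL,
                                  diffusivities = default_diffusivities(),
                                  snr = Inf) {
  check_fractions(fractions)
  if (fractions[3] > 0 && is.null(fiber_dir))
    stop_invalid("fiber_dir required when f_ICA > 0")
  b <- gtab$bvals
  s <- fractions[1] * exp(-b * diffusivities$d_csf) +
       fractions[2] * exp(-b * diffusivities$d_gm)
  if (fractions[3] > 0) {
    v <- fiber_dir / sqrt(sum(fiber_dir^2))
    ct2 <- drop(gtab$bvecs %*% v)^2
    s <- s + fractions[3] *
      exp(-b * (diffusivities$d_rad +
                  (diffusivities$d_ax - diffusivities$d_rad) * ct2))
  }
  if (is.finite(snr)) s <- add_rician_noise(s, 1 / snr)
  s
}

add_rician_noise <- function(s, sigma) {
  n <- length(s)
  sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

## distance from points (n x 3) to a polyline, plus the local unit tangent
## of the nearest segment
polyline_distance <- function(points, centerline) {
  n <- nrow(points)
  best <- rep(Inf, n)
  tang <- matrix(0, n, 3)
  for (k in seq_len(nrow(centerline) - 1)) {
    a <- centerline[k, ]; bb <- centerline[k + 1, ]
    ab <- bb - a
    len2 <- sum(ab^2)
    t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2] +
            (points[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- points[, 1] - (a[1] + t * ab[1])
    dy <- points[, 2] - (a[2] + t * ab[2])
    dz <- points[, 3] - (a[3] + t * ab[3])
    d <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- d < best
    best[hit] <- d[hit]
    tang[hit, ] <- matrix(ab / sqrt(len2), sum(hit), 3, byrow = TRUE)
  }
  list(distance = best, tangent = tang)
}

#' Build a synthetic DWI dataset and its ground truth
#'
#' Rasterizes bundles, lesions and background onto the grid, simulates the
#' per-voxel multi-shell signal, and records ground-truth fractions, fiber
#' directions, the WMH mask and response-estimation tissue masks.
#' Overlapping bundles have their fraction triples summed then renormalized;
#' the fiber direction of the bundle with the largest local axonal fraction
#' wins. Lesions override bundle fractions; penumbrae then shift axonal
#' signal to free water in surviving bundle voxels near the lesion.
#'
#' @param spec [phantom_spec()].
#' @param gtab [gradient_table()]; default the two-shell protocol with
#'   10 b = 0 and 64 directions at b = 1500 and 3000 s/mm^2.
#' @return list with `dwi` (class `dwi_dataset`: `data` 4-D array, `gtab`,
#'   `affine`, `brain_mask`) and `truth` (class `phantom_truth`:
#'   `true_fractions` 4-D (x,y,z,3), `fiber_direction` 4-D (x,y,z,3, NA when
#'   absent), `wmh_mask`, `tissue_masks` list wm/gm/csf, `affine`).
#' @export
build_phantom <- function(spec,
                          gtab = make_gradient_table(10, 64, c(1500, 3000))) {
  ras <- rasterize_phantom(spec)
  dims <- spec$grid_shape
  affine <- ras$affine
  mask <- ras$mask

  signal <- simulate_signal_matrix(gtab, ras$frac, ras$fdir,
                                   spec$diffusivities, which(mask))
  if (is.finite(spec$snr)) {
    signal <- with_seed(spec$seed, {
      idx <- which(mask)
      sigma <- 1 / spec$snr
      nm <- length(idx) * length(gtab$bvals)
      signal[idx, ] <- sqrt((signal[idx, ] + rnorm(nm, 0, sigma))^2 +
                              matrix(rnorm(nm, 0, sigma),
                                     length(idx))^2)
      signal
    })
  }
  # signal is nvox x nmeas with voxels in array index order
  data <- array(signal, c(dims, length(gtab$bvals)))

  dwi <- structure(list(data = data, gtab = gtab, affine = affine,
                        brain_mask = array(mask, dims)),
                   class = "dwi_dataset")
  truth <- structure(list(
    true_fractions = array(ras$frac, c(dims, 3)),
    fiber_direction = array(ras$fdir, c(dims, 3)),
    wmh_mask = array(ras$wmh, dims),
    penumbra_mask = array(ras$pen, dims),
    tissue_masks = list(wm = array(ras$wm_mask, dims),
                        gm = array(ras$gm_mask, dims),
                        csf = array(ras$csf_mask, dims)),
    affine = affine), class = "phantom_truth")
  list(dwi = dwi, truth = truth)
}

## rasterize fractions, directions and masks onto the grid (no signal)
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  affine <- make_affine(spec$voxel_size)
  nvox <- prod(dims)
  ctr <- voxel_centers(dims, affine)

  frac <- matrix(spec$background, nvox, 3, byrow = TRUE)
  fdir <- matrix(NA_real_, nvox, 3)
  fica_best <- rep(0, nvox)
  in_bundle <- rep(FALSE, nvox)

  if (spec$csf_corner_mm > 0) {
    csf <- ctr[, 1] < spec$csf_corner_mm & ctr[, 2] < spec$csf_corner_mm &
      ctr[, 3] < spec$csf_corner_mm
    frac[csf, ] <- matrix(c(1, 0, 0), sum(csf), 3, byrow = TRUE)
  } else csf <- rep(FALSE, nvox)

  bundle_sum <- matrix(0, nvox, 3)
  hit_any <- rep(FALSE, nvox)
  for (b in spec$bundles) {
    pd <- polyline_distance(ctr, b$centerline)
    hit <- pd$distance <= b$radius_mm
    bundle_sum[hit, ] <- bundle_sum[hit, , drop = FALSE] +
      matrix(b$fractions, sum(hit), 3, byrow = TRUE)
    take_dir <- hit & (b$fractions[3] > fica_best)
    fdir[take_dir, ] <- pd$tangent[take_dir, , drop = FALSE]
    fica_best[take_dir] <- b$fractions[3]
    hit_any <- hit_any | hit
  }
  if (any(hit_any)) {
    s <- rowSums(bundle_sum[hit_any, , drop = FALSE])
    frac[hit_any, ] <- bundle_sum[hit_any, , drop = FALSE] / s
  }
  in_bundle <- hit_any

  wmh <- rep(FALSE, nvox)
  for (l in spec$lesions) {
    d <- sqrt((ctr[, 1] - l$center_mm[1])^2 + (ctr[, 2] - l$center_mm[2])^2 +
                (ctr[, 3] - l$center_mm[3])^2)
    inside <- d <= l$radius_mm
    lf <- l$fractions
    # axonal lesion signal needs an orientation: off-bundle voxels fold the
    # ICA share into the isotropic intracellular compartment instead
    has_dir <- !is.na(fdir[, 1])
    tgt <- inside & has_dir
    if (any(tgt))
      frac[tgt, ] <- matrix(lf, sum(tgt), 3, byrow = TRUE)
    tgt0 <- inside & !has_dir
    if (any(tgt0))
      frac[tgt0, ] <- matrix(c(lf[1], lf[2] + lf[3], 0), sum(tgt0), 3,
                             byrow = TRUE)
    wmh <- wmh | inside
  }
  pen <- rep(FALSE, nvox)
  for (l in spec$lesions) {
    if (l$penumbra_mm <= 0 || l$penumbra_delta_eci == 0) next
    d <- sqrt((ctr[, 1] - l$center_mm[1])^2 + (ctr[, 2] - l$center_mm[2])^2 +
                (ctr[, 3] - l$center_mm[3])^2)
    rim <- d > l$radius_mm & d <= l$radius_mm + l$penumbra_mm &
      in_bundle & !wmh
    if (!any(rim)) next
    delta <- pmin(l$penumbra_delta_eci, frac[rim, 3])
    frac[rim, 1] <- frac[rim, 1] + delta
    frac[rim, 3] <- frac[rim, 3] - delta
    pen <- pen | rim
  }

  mask <- rep(TRUE, nvox)
  if (!is.null(spec$mask_margin_mm)) {
    near <- rep(FALSE, nvox)
    for (b in spec$bundles)
      near <- near |
        polyline_distance(ctr, b$centerline)$distance <= spec$mask_margin_mm
    for (l in spec$lesions) {
      d <- sqrt((ctr[, 1] - l$center_mm[1])^2 +
                  (ctr[, 2] - l$center_mm[2])^2 +
                  (ctr[, 3] - l$center_mm[3])^2)
      near <- near | d <= spec$mask_margin_mm
    }
    mask <- near | csf
  }

  # single-fiber WM response mask: intact pure-bundle voxels
  wm_mask <- in_bundle & !wmh & !pen & frac[, 3] >= 0.95
  gm_mask <- !in_bundle & !wmh & !csf & frac[, 2] >= 0.5 & mask
  csf_mask <- csf & !wmh

  list(frac = frac, fdir = fdir, wmh = wmh, pen = pen,
       in_bundle = in_bundle, csf = csf, mask = mask,
       wm_mask = wm_mask, gm_mask = gm_mask, csf_mask = csf_mask,
       affine = affine, dims = dims)
}

## vectorized forward model over voxels; rows outside `idx` stay zero
simulate_signal_matrix <- function(gtab, frac, fdir, diff, idx) {
  nvox <- nrow(frac); nmeas <- length(gtab$bvals)
  out <- matrix(0, nvox, nmeas)
  b <- gtab$bvals
  e_csf <- exp(-b * diff$d_csf)
  e_gm <- exp(-b * diff$d_gm)
  f <- frac[idx, , drop = FALSE]
  out[idx, ] <- f[, 1, drop = FALSE] %*% rbind(e_csf) +
    f[, 2, drop = FALSE] %*% rbind(e_gm)
  has_ica <- idx[f[, 3] > 0]
  if (length(has_ica)) {
    dirs <- fdir[has_ica, , drop = FALSE]
    if (anyNA(dirs)) stop_invalid("f_ICA > 0 in a voxel without fiber_dir")
    key <- paste(round(dirs[, 1], 10), round(dirs[, 2], 10),
                 round(dirs[, 3], 10))
    for (k in unique(key)) {
      sel <- has_ica[key == k]
      v <- fdir[sel[1], ]
      ct2 <- drop(gtab$bvecs %*% v)^2
      e_wm <- exp(-b * (diff$d_rad + (diff$d_ax - diff$d_rad) * ct2))
      out[sel, ] <- out[sel, , drop = FALSE] +
        frac[sel, 3] %*% rbind(e_wm)
    }
  }
  out
}
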