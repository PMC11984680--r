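## Subject-specific lesionometry: filter the whole-volume tractogram to the
## streamlines traversing WMH voxels, rasterize their track density, and
## keep voxels crossed by at least `min_tracts` distinct lesioned
## streamlines, excluding the WMH itself. ROI microstructure statistics are
## unweighted voxel means of the three signal fractions; lesion load is the
## WMH volume divided by the ROI volume.

#' Construct a lesion (WMH) mask object
#'
#' @param mask logical or 0/1 3-D array on the DWI grid.
#' @param affine 4x4 grid-to-world affine shared with the DWI.
#' @return object of class `lesion_mask` with `mask`, `affine`,
#'   `volume_mm3`.
#' @export
lesion_mask <- function(mask, affine) {
  mask <- array(as.logical(mask), dim(mask))
  structure(list(mask = mask, affine = affine,
                 volume_mm3 = sum(mask) * voxel_volume(affine)),
            class = "lesion_mask")
}

#' Select the streamlines that traverse a WMH
#'
#' @param tractogram a `tractogram`.
#' @param wmh a [lesion_mask()] on the same grid/affine.
#' @return the subset `tractogram` (order and identity preserved), with
#'   attribute `selected` giving the original indices.
#' @export
select_lesioned_streamlines <- function(tractogram, wmh) {
  stopifnot(inherits(wmh, "lesion_mask"))
  check_affine_match(tractogram$affine, wmh$affine, "tractogram/WMH mask")
  vox <- streamline_voxels(tractogram, dim(wmh$mask))
  wm_idx <- which(wmh$mask)
  hit <- vapply(vox, function(v) any(v %in% wm_idx), TRUE)
  out <- tractogram
  out$streamlines <- tractogram$streamlines[hit]
  attr(out, "selected") <- which(hit)
  out
}

#' Build the lesionometry ROI from lesion-filtered streamlines
#'
#' `ROI = { v : TD_subset(v) >= min_tracts } \\ WMH`, each streamline
#' counted once per voxel ("separate tracts").
#'
#' @param subset `tractogram` of lesioned streamlines
#'   (see [select_lesioned_streamlines()]).
#' @param wmh [lesion_mask()].
#' @param min_tracts minimum distinct lesioned streamlines per voxel
#'   (default 10, the published threshold).
#' @return object of class `lesionometry_roi`: `mask`, `affine`,
#'   `min_tracts`, `volume_mm3`, `lesion_load`, and (after
#'   [roi_statistics()]) `mean_f_ECI`, `mean_f_ICI`, `mean_f_ICA`;
#'   `empty` flags subjects whose ROI has no voxels.
#' @export
build_lesionometry_roi <- function(subset, wmh, min_tracts = 10) {
  if (min_tracts < 1) stop_invalid("min_tracts must be >= 1")
  stopifnot(inherits(wmh, "lesion_mask"))
  check_affine_match(subset$affine, wmh$affine, "tractogram/WMH mask")
  dims <- dim(wmh$mask)
  td <- if (length(subset$streamlines))
    track_density_map(subset, dims) else array(0L, dims)
  roi <- td >= min_tracts & !wmh$mask
  stopifnot(!any(roi & wmh$mask)) # disjointness asserted, not assumed
  structure(list(mask = roi, affine = wmh$affine,
                 min_tracts = as.integer(min_tracts),
                 volume_mm3 = sum(roi) * voxel_volume(wmh$affine),
                 lesion_load = lesion_load_value(wmh$volume_mm3,
                                                sum(roi) *
                                                  voxel_volume(wmh$affine)),
                 mean_f_ECI = NA_real_, mean_f_ICI = NA_real_,
                 mean_f_ICA = NA_real_, empty = !any(roi)),
            class = "lesionometry_roi")
}

#' Fill ROI microstructure statistics
#'
#' Unweighted voxel means of the three signal fractions over ROI voxels.
#' An empty ROI leaves the statistics missing and flags the subject.
#'
#' @param roi `lesionometry_roi`.
#' @param fractions `fraction_field` from [fit_ss3t_field()].
#' @return the completed `lesionometry_roi`.
#' @export
roi_statistics <- function(roi, fractions) {
  stopifnot(inherits(roi, "lesionometry_roi"))
  check_affine_match(roi$affine, fractions$affine, "ROI/fraction maps")
  if (roi$empty) return(roi)
  idx <- which(roi$mask)
  f <- matrix(fractions$f, ncol = 3)[idx, , drop = FALSE]
  if (anyNA(f))
    stop("fractions undefined on ", sum(!stats::complete.cases(f)),
         " ROI voxel(s); ROI must lie inside the fitted mask")
  m <- colMeans(f)
  roi$mean_f_ECI <- m[1]; roi$mean_f_ICI <- m[2]; roi$mean_f_ICA <- m[3]
  roi
}

lesion_load_value <- function(wmh_mm3, roi_mm3) {
  if (wmh_mm3 == 0) return(0)
  if (roi_mm3 == 0) return(NA_real_)
  wmh_mm3 / roi_mm3
}

#' Lesion load: WMH volume over lesionometry-ROI volume
#'
#' @param wmh [lesion_mask()].
#' @param roi `lesionometry_roi` (must exclude the WMH by construction).
#' @return non-negative ratio; 0 when the WMH is empty; `NA` (missing,
#'   never an error) when the ROI is empty.
#' @export
lesion_load <- function(wmh, roi) {
  stopifnot(inherits(wmh, "lesion_mask"), inherits(roi, "lesionometry_roi"))
  lesion_load_value(wmh$volume_mm3, roi$volume_mm3)
}

#' @export
print.lesionometry_roi <- function(x, ...) {
  cat("lesionometry_roi:", sum(x$mask), "voxels (",
      round(x$volume_mm3, 1), "mm^3 ), min_tracts =", x$min_tracts,
      ", lesion load =", signif(x$lesion_load, 3), "\n")
  if (!is.na(x$mean_f_ECI))
    cat(sprintf("  mean fractions: ECI %.3f ICI %.3f ICA %.3f\n",
                x$mean_f_ECI, x$mean_f_ICI, x$mean_f_ICA))
  invisible(x)
}
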