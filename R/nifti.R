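## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
## Scope: the subset this pipeline emits - 3-D/4-D volumes, float32 /
## int32 / uint8, little-endian, sform affine. The in-package affine maps
## continuous grid coordinates (voxel i = [i, i+1), centre i + 0.5) to
## world mm; NIfTI's sform maps integer voxel indices to centre positions,
## so the offset column is shifted by half a voxel on write and read.

nifti_datatypes <- list(uint8 = list(code = 2L, size = 1L, what = "integer"),
                        int32 = list(code = 8L, size = 4L, what = "integer"),
                        float32 = list(code = 16L, size = 4L,
                                       what = "numeric"))

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' @param img numeric/logical array (3-D or 4-D).
#' @param path output `.nii` or `.nii.gz` path.
#' @param affine 4x4 grid-to-world affine (corner convention, see above).
#' @param datatype one of `"float32"`, `"int32"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, affine = diag(4), datatype = "float32") {
  dt <- nifti_datatypes[[datatype]]
  if (is.null(dt)) stop("format error: unsupported datatype ", datatype)
  nd <- length(dim(img))
  stopifnot(nd %in% c(3, 4))
  dims <- dim(img)
  con <- open_conn(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  # sform maps integer index -> voxel centre
  srow <- affine[1:3, , drop = FALSE]
  srow[, 4] <- srow[, 4] + affine[1:3, 1:3] %*% rep(0.5, 3)
  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))

  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused
  wi(c(nd, dims, rep(1, 7 - nd)), 2)           # dim[8]
  wf(c(0, 0, 0))                               # intent_p1..p3
  wi(0, 2)                                     # intent_code
  wi(dt$code, 2)                               # datatype
  wi(8L * dt$size, 2)                          # bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, pixdim, rep(1, 7 - length(pixdim)))) # pixdim[8] (qfac 1)
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt
  wf(c(0, 0, 0))                               # cal_max, cal_min, slice_dur
  wf(0)                                        # toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  writeBin(raw(104), con)                      # descrip + aux_file
  wi(c(0, 2), 2)                               # qform_code 0, sform_code 2
  wf(rep(0, 6))                                # quatern b c d, qoffset x y z
  wf(t(srow))                                  # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  vals <- as.vector(img)
  if (dt$what == "integer") wi(vals, dt$size) else wf(vals)
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or compatible)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array) and `affine` (4x4, corner convention).
#' @export
read_nifti <- function(path) {
  con <- open_conn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n, size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348) stop("format error: not a NIfTI-1 file: ", path)
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  code <- ri(70, 2)
  dt <- Filter(function(d) d$code == code, nifti_datatypes)
  if (!length(dt)) stop("format error: unsupported NIfTI datatype ", code)
  dt <- dt[[1]]
  vox_offset <- rf(108)
  srow <- matrix(rf(280, 12), 3, 4, byrow = TRUE)
  affine <- rbind(srow, c(0, 0, 0, 1))
  affine[1:3, 4] <- affine[1:3, 4] - affine[1:3, 1:3] %*% rep(0.5, 3)
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, endian = "little",
                  signed = dt$size > 2)
  list(data = array(vals, dims), affine = affine)
}
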