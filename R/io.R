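## FSL-dialect bvals/bvecs, MRtrix TCK tractograms, TSV tables, and the
## composite DWI reader/writer.

#' Write FSL-style bvals/bvecs text files
#'
#' `bvals`: one space-separated row. `bvecs`: three rows (x, y, z).
#'
#' @param gtab [gradient_table()].
#' @param bvals_path,bvecs_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(gtab, bvals_path, bvecs_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "),
             bvals_path)
  writeLines(apply(t(gtab$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

#' Read FSL-style bvals/bvecs
#' @param bvals_path,bvecs_path input paths.
#' @return [gradient_table()].
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  rows <- lapply(readLines(bvecs_path), function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  if (length(rows) != 3)
    stop("format error: bvecs must have 3 rows, found ", length(rows))
  if (length(unique(lengths(rows))) != 1 ||
      length(rows[[1]]) != length(bvals))
    stop("format error: bvals/bvecs lengths mismatch")
  gradient_table(bvals, cbind(rows[[1]], rows[[2]], rows[[3]]))
}

#' Write a DWI dataset (NIfTI + bvals/bvecs + mask)
#' @param dwi `dwi_dataset`.
#' @param prefix output path prefix; writes `<prefix>_dwi.nii`,
#'   `<prefix>.bvals`, `<prefix>.bvecs`, `<prefix>_mask.nii`.
#' @return named character vector of paths, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  paths <- c(dwi = paste0(prefix, "_dwi.nii"),
             bvals = paste0(prefix, ".bvals"),
             bvecs = paste0(prefix, ".bvecs"),
             mask = paste0(prefix, "_mask.nii"))
  write_nifti(dwi$data, paths["dwi"], dwi$affine, "float32")
  write_bvals_bvecs(dwi$gtab, paths["bvals"], paths["bvecs"])
  write_nifti(dwi$brain_mask + 0L, paths["mask"], dwi$affine, "uint8")
  invisible(paths)
}

#' Read a DWI dataset from NIfTI + bvals/bvecs (+ optional mask)
#' @param dwi_path 4-D NIfTI.
#' @param bvals_path,bvecs_path gradient table files.
#' @param mask_path optional mask NIfTI (must share the affine).
#' @return `dwi_dataset`.
#' @export
read_dwi <- function(dwi_path, bvals_path, bvecs_path, mask_path = NULL) {
  nii <- read_nifti(dwi_path)
  gtab <- read_bvals_bvecs(bvals_path, bvecs_path)
  if (dim(nii$data)[4] != length(gtab$bvals))
    stop("format error: DWI volume count (", dim(nii$data)[4],
         ") does not match gradient table length (", length(gtab$bvals), ")")
  mask <- if (is.null(mask_path)) {
    array(TRUE, dim(nii$data)[1:3])
  } else {
    m <- read_nifti(mask_path)
    check_affine_match(nii$affine, m$affine, "DWI/mask")
    array(m$data != 0, dim(m$data))
  }
  structure(list(data = nii$data, gtab = gtab, affine = nii$affine,
                 brain_mask = mask), class = "dwi_dataset")
}

#' Write a tractogram in MRtrix TCK format
#'
#' Float32 little-endian triplets; streamlines separated by NaN triplets,
#' stream terminated by an Inf triplet.
#'
#' @param tractogram a `tractogram`.
#' @param path output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tractogram, path) {
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           paste0("count: ", length(tractogram$streamlines)),
           paste0("step_size: ", format(tractogram$step_size)),
           "lesionometry_affine: corner")
  # the offset line must state the total header size, including itself
  n0 <- sum(nchar(hdr) + 1L) + nchar("END") + 1L
  off_line <- function(o) paste0("file: . ", o)
  off <- n0 + nchar(off_line(0)) + 1L
  while (nchar(off_line(off)) + 1L + n0 != off)
    off <- n0 + nchar(off_line(off)) + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr[1:2], off_line(off), hdr[3:length(hdr)], "END"), con,
             sep = "\n")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  for (s in tractogram$streamlines) {
    wf(as.numeric(t(s)))
    wf(rep(NaN, 3))
  }
  wf(rep(Inf, 3))
  invisible(path)
}

#' Read an MRtrix TCK file
#' @param path `.tck` path.
#' @param affine grid-to-world affine to attach (TCK stores none).
#' @return a `tractogram` (seed_count/rng_seed are `NA`: provenance is not
#'   stored in TCK).
#' @export
read_tck <- function(path, affine = diag(4)) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, 1)
  if (!identical(first, "mrtrix tracks"))
    stop("format error: not a TCK file (bad magic line): ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("format error: TCK header missing END")
    if (ln == "END") break
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) fields[[kv[1]]] <- kv[2]
  }
  if (is.null(fields$file))
    stop("format error: TCK header missing file offset")
  off <- as.integer(strsplit(fields$file, " ")[[1]][2])
  seek(con, off)
  raw <- readBin(con, "numeric", file.size(path), size = 4,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  ends <- which(!is.finite(m[, 1]))
  streamlines <- list()
  start <- 1
  for (e in ends) {
    if (is.infinite(m[e, 1])) break
    if (e > start)
      streamlines[[length(streamlines) + 1]] <- m[start:(e - 1), ,
                                                  drop = FALSE]
    start <- e + 1
  }
  step <- as.numeric(fields$step_size %||% NA)
  new_tractogram(streamlines, affine, NA_integer_, NA_integer_, step)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a fraction field as three NIfTI maps
#' @param fractions `fraction_field`.
#' @param prefix path prefix; writes `<prefix>_f{eci,ici,ica}.nii`.
#' @return named paths, invisibly.
#' @export
write_fractions <- function(fractions, prefix) {
  comp <- c(feci = 1, fici = 2, fica = 3)
  paths <- vapply(names(comp), function(nm) {
    p <- paste0(prefix, "_", nm, ".nii")
    vol <- fractions$f[, , , comp[[nm]]]
    vol[is.na(vol)] <- 0
    write_nifti(vol, p, fractions$affine, "float32")
    p
  }, "")
  invisible(paths)
}

#' Write an FOD coefficient field as 4-D NIfTI
#' @param fod `fod_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fod <- function(fod, path) {
  write_nifti(fod$coef, path, fod$affine, "float32")
  invisible(path)
}
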