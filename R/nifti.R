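# Minimal NIfTI-1 I/O. No R NIfTI reader is available in the supported
# dependency set, so this implements the subset the pipeline consumes:
# single-file .nii / .nii.gz, 3-D volumes, datatypes uint8 / int16 / int32
# / float32 / float64, scl_slope/scl_inter scaling, and the sform affine
# (fallback: diagonal pixdim). qform quaternions are not supported.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `list(data = 3-D array, affine = 4 x 4 voxel-to-world matrix
#'   (mm), dim = integer dims)`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  rd <- function(what, n, off, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  sizeof <- rd("integer", 1, 0, 4)
  if (sizeof != 348) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  dim <- rd("integer", 8, 40, 2)
  datatype <- rd("integer", 1, 70, 2)
  pixdim <- rd("double", 8, 76, 4)
  vox_offset <- rd("double", 1, 108, 4)
  scl_slope <- rd("double", 1, 112, 4)
  scl_inter <- rd("double", 1, 116, 4)
  sform_code <- rd("integer", 1, 254, 2)
  srow <- matrix(rd("double", 12, 280, 4), nrow = 3, byrow = TRUE)
  nd <- dim[1]
  if (nd < 3) stop("expected a 3-D volume")
  dims <- dim[2:4]
  nvox <- prod(dims)
  spec <- switch(as.character(datatype),
    "2" = list(what = "integer", size = 1, signed = FALSE),
    "4" = list(what = "integer", size = 2, signed = TRUE),
    "8" = list(what = "integer", size = 4, signed = TRUE),
    "16" = list(what = "double", size = 4, signed = TRUE),
    "64" = list(what = "double", size = 8, signed = TRUE),
    stop("unsupported NIfTI datatype: ", datatype))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = "little")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- if (sform_code > 0) {
    rbind(srow, c(0, 0, 0, 1))
  } else {
    pd <- pixdim[2:4]
    pd[pd == 0] <- 1
    rbind(cbind(diag(pd), c(0, 0, 0)), c(0, 0, 0, 1))
  }
  list(data = array(vals, dim = dims), affine = affine, dim = dims)
}

#' Write a NIfTI-1 volume (float32, sform affine)
#'
#' @param data 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-world matrix (mm); default identity.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4)) {
  stopifnot(length(dim(data)) == 3L, all(dim(affine) == c(4, 4)))
  dims <- dim(data)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  buf <- raw(348)
  put <- function(x, off, size, what = "integer") {
    b <- writeBin(if (what == "integer") as.integer(x) else as.double(x),
                  raw(), size = size, endian = "little")
    buf[(off + 1):(off + length(b))] <<- b
    invisible(NULL)
  }
  put(348L, 0, 4)
  put(c(3L, dims, 1L, 1L, 1L, 1L), 40, 2)
  put(16L, 70, 2)                       # float32
  put(32L, 72, 2)                       # bitpix
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  put(c(1, pd, 1, 1, 1, 1), 76, 4, "double")
  put(352, 108, 4, "double")            # vox_offset
  put(1, 112, 4, "double")              # scl_slope
  put(0, 116, 4, "double")              # scl_inter
  put(1L, 254, 2)                       # sform_code
  put(as.numeric(t(affine[1:3, ])), 280, 4, "double")
  buf[345:348] <- as.raw(c(0x6e, 0x2b, 0x31, 0x00))  # "n+1"
  writeBin(buf, con)
  writeBin(raw(4), con)                 # extension flag
  writeBin(as.double(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a subject from a PET volume and a multi-label mask
#'
#' Voxels with a nonzero mask label become points at world-space mm
#' coordinates (via the volume affine), with SUV taken from the PET volume
#' and labels resolved through the integer-to-name map.
#'
#' @param pet_path NIfTI path of the SUV volume.
#' @param mask_path NIfTI path of the integer multi-label mask (same grid
#'   and affine).
#' @param label_map Named character vector: names are integer label ids
#'   (as strings), values are fine organ labels.
#' @param subject_id Subject identifier.
#' @return A [labeled_point_cloud()].
#' @export
read_nifti_subject <- function(pet_path, mask_path, label_map,
                               subject_id = "subject") {
  pet <- read_nifti(pet_path)
  mask <- read_nifti(mask_path)
  if (!identical(pet$dim, mask$dim)) {
    stop("PET and mask grids differ: ", paste(pet$dim, collapse = "x"),
         " vs ", paste(mask$dim, collapse = "x"))
  }
  if (max(abs(pet$affine - mask$affine)) > 1e-4) {
    stop("PET and mask affines differ")
  }
  ids <- round(as.numeric(mask$data))
  sel <- which(ids != 0)
  if (!length(sel)) stop("mask contains no labeled voxels")
  found <- unique(ids[sel])
  unknown <- setdiff(as.character(found), names(label_map))
  if (length(unknown)) {
    stop("unknown label id(s) in mask: ", paste(unknown, collapse = ", "))
  }
  idx <- arrayInd(sel, pet$dim) - 1L   # 0-based voxel indices
  world <- t(pet$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  labeled_point_cloud(world, as.numeric(pet$data)[sel],
                      unname(label_map[as.character(ids[sel])]), subject_id)
}
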