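# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI package is assumed available; this reader covers the subset of the
# format the package produces and consumes: 3-D volumes, little- or big-endian
# headers, datatypes uint8/int16/int32/float32/float64, scl_slope/scl_inter
# rescaling, and the sform affine (falling back to pixdim spacing when no
# sform is set).  Writing always emits float32 with an sform.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a numeric
#' array plus its 4x4 voxel-to-world affine.  Only 3-D volumes are supported;
#' trailing singleton dimensions are dropped.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (3-D numeric array), `affine`
#'   (4x4 matrix) and `pixdim` (length-3 voxel size in mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_parse(sprintf("truncated NIfTI header: %s", path))
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop_parse(sprintf("not a NIfTI-1 file: %s", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_parse(sprintf("bad NIfTI magic '%s': %s", magic, path))

  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2L * n)], "integer",
                                     n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4L * n)], "double",
                                     n = n, size = 4L, endian = endian)

  dim8 <- rd_i16(40L, 8L)
  ndim <- dim8[1]
  if (ndim < 3L || ndim > 4L)
    stop_parse(sprintf("expected a 3-D or 4-D volume, got %d-D: %s", ndim, path))
  shape <- dim8[2:(ndim + 1L)]
  if (length(shape) == 4L && shape[4] == 1L) shape <- shape[1:3]

  datatype <- rd_i16(70L, 1L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop_parse(sprintf("unsupported NIfTI datatype %d: %s", datatype, path))

  pixdim <- rd_f32(76L, 8L)[2:4]
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  srow <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L))

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  nvox <- prod(shape)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop_parse(sprintf("truncated voxel data: %s", path))
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }

  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else {
    diag(affine)[1:3] <- ifelse(pixdim == 0, 1, pixdim)
  }
  list(data = array(vals, dim = shape), affine = affine,
       pixdim = ifelse(pixdim == 0, 1, abs(pixdim)))
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D (or 4-D, e.g. a two-volume model image) numeric array as a
#' single-file NIfTI-1 image (float32, sform set from `affine`).
#' Compression is chosen from the file extension.
#'
#' @param data 3-D or 4-D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix (default: identity, 1 mm voxels).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4)) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop_parse("write_nifti expects a 3-D or 4-D array")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  shape <- dim(data)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)

  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  dim8 <- c(nd, shape, rep(1L, 7L - length(shape)))
  w_i32(348L)                         # sizeof_hdr
  w_raw(36L)                          # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(dim8)                         # dim
  w_raw(14L)                          # intent_p1..3, intent_code
  w_i16(16L)                          # datatype = float32
  w_i16(32L)                          # bitpix
  w_i16(0L)                           # slice_start
  w_f32(c(1, vox, 1, 1, 1, 1))        # pixdim (qfac = 1)
  w_f32(352)                          # vox_offset
  w_f32(1); w_f32(0)                  # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                    # glmax, glmin
  w_raw(80L + 24L)                    # descrip, aux_file
  w_i16(c(0L, 2L))                    # qform_code = 0, sform_code = 2 (aligned)
  w_f32(rep(0, 6))                    # quatern b,c,d + qoffset x,y,z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                           # extension flag
  w_f32(as.double(data))
  invisible(path)
}
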