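# Minimal single-file NIfTI-1 (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the deployment environment, so the small
# subset of the format the pipeline needs is implemented here directly:
# single-file little-endian NIfTI-1, datatypes uint8 / int16 / int32 /
# float32 / float64, diagonal sform built from the voxel dimensions, and the
# common-space tag carried in the 80-byte descrip field. Big-endian files are
# byte-swapped on read. Extensions, qform quaternions and scl slopes other
# than the identity are not interpreted.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE)   # float64
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file `.nii` or `.nii.gz` image. 2D single-slice images are
#' promoted to a 3D lattice with third dimension 1. The `descrip` header
#' field, when non-empty, is taken as the common-space tag.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param space_tag Optional override for the space tag; when supplied and the
#'   file carries a different non-empty tag, an error naming both spaces is
#'   raised (the session's declared common space must match the file's).
#' @return A [volume()].
#' @export
read_volume <- function(path, space_tag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    endian <- "big"
    b <- writeBin(sizeof_hdr, raw(), size = 4, endian = "little")
    if (!identical(readBin(rev(b), "integer", 1, size = 4, endian = "little"), 348L))
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  hdr_rest <- readBin(con, "raw", 348 - 4)
  hdr <- c(writeBin(348L, raw(), size = 4, endian = endian), hdr_rest)
  rd <- function(off, what, n, size) # off = byte offset within header
    readBin(hdr[(off + 1):(off + n * size)], what, n, size = size,
            endian = endian, signed = TRUE)
  dim_field <- rd(40, "integer", 8, 2)
  ndim <- dim_field[1]
  if (ndim < 2 || ndim > 3) stop("unsupported NIfTI dimensionality: ", ndim)
  dims <- dim_field[2:(1 + ndim)]
  if (ndim == 2) dims <- c(dims, 1L)
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  voxel_mm <- pixdim[2:4]
  voxel_mm[voxel_mm <= 0 | !is.finite(voxel_mm)] <- 1
  if (ndim == 2) voxel_mm[3] <- 1
  vox_offset <- rd(108, "double", 1, 4)
  descrip_raw <- hdr[149:228]
  descrip <- rawToChar(descrip_raw[seq_len(max(0, which(descrip_raw != as.raw(0))))])
  file_tag <- if (nzchar(descrip)) descrip else "common"
  if (!is.null(space_tag) && nzchar(descrip) && !identical(space_tag, descrip))
    stop(sprintf("space mismatch: file '%s' is in space '%s' but the session declares '%s'",
                 path, descrip, space_tag))
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n_vox <- prod(dims)
  data <- readBin(con, dt$what, n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) != n_vox) stop("truncated NIfTI data in ", path)
  data <- array(as.double(data), dim = dims)
  volume(data, voxel_mm = voxel_mm, space_tag = space_tag %||% file_tag)
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file little-endian `.nii` (or `.nii.gz` when the path ends
#' in `.gz`). The space tag is stored in the `descrip` field and a diagonal
#' sform is built from the voxel dimensions, so a write/read round trip
#' preserves the lattice, voxel sizes and space tag exactly.
#'
#' @param vol A [volume()], or a logical/integer 3D array (written as uint8 /
#'   int32) when `voxel_mm`/`space_tag` are supplied.
#' @param path Output path.
#' @param datatype One of `"float64"`, `"float32"`, `"int32"`, `"int16"`,
#'   `"uint8"`. Defaults to `float64` for numeric data, `uint8` for logical,
#'   `int32` for integer arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  if (inherits(vol, "deficit_mask"))
    vol <- volume(array(as.double(vol$mask), dim(vol$mask)),
                  voxel_mm = vol$voxel_mm, space_tag = vol$space_tag)
  if (inherits(vol, "label_volume"))
    vol <- volume(array(as.double(vol$labels), dim(vol$labels)),
                  voxel_mm = vol$voxel_mm, space_tag = vol$space_tag)
  if (!inherits(vol, "volume")) stop("vol must be a volume")
  data <- vol$data
  if (is.null(datatype)) {
    datatype <- if (all(data == round(data) | !is.finite(data)) &&
                    max(abs(data), 0, na.rm = TRUE) <= .Machine$integer.max) {
      if (all(data %in% c(0, 1) | !is.finite(data))) "uint8" else "int32"
    } else "float64"
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  dt <- NIFTI_DTYPES[[as.character(code)]]
  bitpix <- dt$size * 8L
  dims <- dim(data)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_chr <- function(s, n) {
    r <- charToRaw(substr(s, 1, n))
    writeBin(c(r, raw(n - length(r))), con)
  }
  w_i32(348)                      # sizeof_hdr
  w_chr("", 10); w_chr("", 18)    # data_type, db_name (unused)
  w_i32(0); w_i16(0); w_chr("r", 1); w_chr("", 1) # extents, session_error, regular, dim_info
  w_i16(c(3L, dims, 1L, 1L, 1L, 1L))              # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)     # intent_p1-3, intent_code
  w_i16(code); w_i16(bitpix); w_i16(0)            # datatype, bitpix, slice_start
  w_f32(c(1, vol$voxel_mm, 1, 0, 0, 0))           # pixdim[8]
  w_f32(352)                      # vox_offset
  w_f32(1); w_f32(0)              # scl_slope, scl_inter
  w_i16(0); w_chr("", 1)          # slice_end, slice_code
  writeBin(as.raw(2L), con)       # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))            # cal_max, cal_min, slice_duration, toffset
  w_i32(0); w_i32(0)              # glmax, glmin
  w_chr(vol$space_tag, 80)        # descrip <- space tag
  w_chr("", 24)                   # aux_file
  w_i16(0); w_i16(2)              # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))      # quatern b,c,d + qoffset x,y,z
  w_f32(c(vol$voxel_mm[1], 0, 0, 0))  # srow_x
  w_f32(c(0, vol$voxel_mm[2], 0, 0))  # srow_y
  w_f32(c(0, 0, vol$voxel_mm[3], 0))  # srow_z
  w_chr("", 16)                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)      # magic
  writeBin(raw(4), con)           # extension flag
  vec <- as.vector(data)
  if (dt$what == "integer") {
    vec[!is.finite(vec)] <- 0
    writeBin(as.integer(round(vec)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vec), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
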