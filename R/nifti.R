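# Minimal NIfTI-1 single-file (.nii, uncompressed) I/O.
#
# Only the subset the pipeline emits is supported: 3D/4D volumes, dtypes
# uint8 / int16 / int32 / float32 / float64, diagonal affine (spacing +
# origin, voxel-centre convention, sform code 1). No pre-installed R
# package provides the format, hence this self-contained implementation.

nifti_dtypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE))

#' Write a volume as an uncompressed NIfTI-1 file
#'
#' @param x a `scalar_image`, `label_volume`, or a plain 3D/4D array.
#' @param path output file path (conventionally `.nii`).
#' @param dtype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; default picks `float64` for scalar data and the smallest
#'   integer type that fits for label data.
#' @param spacing,origin grid geometry, taken from `x` when it is a
#'   headforge container.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, dtype = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (inherits(x, "scalar_image")) {
    arr <- x$values; spacing <- x$spacing; origin <- x$origin
    if (is.null(dtype)) dtype <- "float64"
  } else if (inherits(x, "label_volume")) {
    arr <- x$labels; spacing <- x$spacing; origin <- x$origin
    if (is.null(dtype)) dtype <- if (max(arr) <= 255L) "uint8" else "int32"
  } else {
    arr <- x
    if (is.null(dtype)) dtype <- if (is.integer(arr)) "int32" else "float64"
  }
  stopifnot(is.array(arr), length(dim(arr)) %in% c(3L, 4L))
  dt <- nifti_dtypes[[dtype]]
  if (is.null(dt)) stop("unsupported dtype: ", dtype)
  d <- dim(arr)
  ndim <- length(d)
  dim_field <- integer(8)
  dim_field[1] <- ndim
  dim_field[2:(1 + ndim)] <- d
  if (ndim < 7) dim_field[(2 + ndim):8] <- 1L
  pixdim <- numeric(8)
  pixdim[2:4] <- spacing
  pixdim[5:8] <- 1

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  writeBin(raw(35), con)           # data_type[10] db_name[18] extents[4]
                                   # session_error[2] regular[1]
  writeBin(as.raw(0L), con)        # dim_info
  wi(dim_field, 2)                 # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(dt$code, 2)                   # datatype
  wi(dt$bitpix, 2)                 # bitpix
  wi(0L, 2)                        # slice_start
  wf(pixdim)                       # pixdim[8]
  wf(352)                          # vox_offset
  wf(c(1, 0))                      # scl_slope, scl_inter
  wi(0L, 2)                        # slice_end
  writeBin(as.raw(c(0L, 10L)), con)  # slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                # cal_max cal_min slice_duration toffset
  wi(c(0L, 0L), 4)                 # glmax glmin
  wc("headforge", 80)              # descrip
  wc("", 24)                       # aux_file
  wi(0L, 2)                        # qform_code
  wi(1L, 2)                        # sform_code
  wf(c(0, 0, 0, 0, 0, 0))         # quatern b,c,d qoffset x,y,z
  wf(c(spacing[1], 0, 0, origin[1]))  # srow_x
  wf(c(0, spacing[2], 0, origin[2]))  # srow_y
  wf(c(0, 0, spacing[3], origin[3]))  # srow_z
  wc("", 16)                       # intent_name
  wc("n+1", 4)                     # magic
  writeBin(raw(4), con)            # extension flag
  v <- as.vector(arr)
  if (dt$what == "integer") {
    v <- as.integer(round(v))
    if (dtype == "uint8") {
      writeBin(as.raw(v), con)
    } else {
      writeBin(v, con, size = dt$size, endian = "little")
    }
  } else {
    writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file written by [write_nifti()] or a
#' compatible tool
#'
#' @param path `.nii` file path.
#' @param as one of `"auto"`, `"scalar_image"`, `"label_volume"`,
#'   `"array"`.
#' @return a `scalar_image`, `label_volume`, or array (4D data always comes
#'   back as an array with attributes `spacing` and `origin`).
#' @export
read_nifti <- function(path, as = "auto") {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file")
  invisible(readBin(con, "raw", n = 36))
  dim_field <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))
  datatype <- ri(1, 2)
  invisible(ri(1, 2)); invisible(ri(1, 2))
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl <- rf(2)
  invisible(ri(1, 2)); invisible(readBin(con, "raw", n = 2))
  invisible(rf(4)); invisible(ri(2, 4))
  invisible(readBin(con, "raw", n = 104))
  invisible(ri(1, 2)); sform <- ri(1, 2)
  invisible(rf(6))
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  invisible(readBin(con, "raw", n = 20))
  nm <- names(which(vapply(nifti_dtypes, function(d) d$code == datatype, TRUE)))
  if (length(nm) != 1) stop("unsupported NIfTI datatype code: ", datatype)
  dt <- nifti_dtypes[[nm]]
  ndim <- dim_field[1]
  d <- dim_field[2:(1 + ndim)]
  n <- prod(d)
  seek(con, where = vox_offset, origin = "start")
  v <- if (nm == "uint8") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
            endian = "little")
  }
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) v <- v * scl[1] + scl[2]
  arr <- array(v, dim = d)
  spacing <- if (sform == 1L) diag(srow[, 1:3]) else pixdim[2:4]
  origin <- if (sform == 1L) srow[, 4] else c(0, 0, 0)
  if (ndim == 4L || as == "array") {
    attr(arr, "spacing") <- spacing
    attr(arr, "origin") <- origin
    return(arr)
  }
  if (as == "label_volume" || (as == "auto" && dt$what == "integer")) {
    label_volume(arr, spacing = spacing, origin = origin)
  } else {
    scalar_image(arr * 1.0, spacing = spacing, origin = origin)
  }
}
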