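# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is assumed; this covers exactly what the pipeline needs:
# single-file .nii / .nii.gz, 3D or 4D, datatypes uint8 / int16 / int32 /
# float32 / float64, scl_slope/scl_inter honoured on read. Orientation
# metadata is passed through untouched (the extraction step requires
# voxel-space-aligned inputs and never resamples).

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE))

#' Write a 3D/4D array as a NIfTI-1 file
#'
#' Integer arrays are stored as int32, doubles as float64. Files ending in
#' `.gz` are gzip-compressed. Voxel dimensions are written as 1.
#'
#' @param x 3D or 4D numeric/integer array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  nd <- length(dim(x))
  if (is.null(dim(x)) || nd < 3L || nd > 4L)
    stop("write_nifti: x must be a 3D or 4D array")
  int_data <- is.integer(x) || (is.numeric(x) && all(x == round(x)) &&
                                max(abs(x)) < 2^31 - 1)
  datatype <- if (int_data) 8L else 64L
  bitpix <- if (int_data) 32L else 64L

  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(x)
  dims[dims == 0L] <- 1L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(v, size) writeBin(v, con, size = size, endian = "little")
  wb(348L, 4L)                                   # sizeof_hdr
  wb(raw(36), 1L)                                # unused + dim_info
  wb(as.integer(dims), 2L)                       # dim[8]
  wb(numeric(3), 4L)                             # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(datatype, 2L); wb(bitpix, 2L); wb(0L, 2L)   # datatype,bitpix,slice_start
  wb(c(1, rep(1, 7)), 4L)                        # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(1, 4L); wb(0, 4L)                           # scl_slope, scl_inter
  wb(0L, 2L); wb(raw(2), 1L)                     # slice_end, codes
  wb(numeric(4), 4L)                             # cal_max..slice_duration...
  wb(0L, 4L); wb(0L, 4L)                         # glmax, glmin
  wb(raw(80 + 24), 1L)                           # descrip, aux_file
  wb(0L, 2L); wb(0L, 2L)                         # qform_code, sform_code
  wb(numeric(6), 4L)                             # quatern/qoffset
  srow <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  wb(as.numeric(t(srow)), 4L)                    # srow_x/y/z
  wb(raw(16), 1L)                                # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  wb(raw(1), 1L)                                 # magic NUL
  wb(raw(4), 1L)                                 # extension flag
  if (int_data) {
    wb(as.integer(x), 4L)
  } else {
    wb(as.numeric(x), 8L)
  }
  invisible(path)
}

#' Read a NIfTI-1 file into an array
#'
#' @param path Path to a `.nii` or `.nii.gz` single-file NIfTI-1 image.
#' @return Numeric (or integer) array with the image dimensions.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")  # reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("read_nifti: truncated header in ", path)
  grab <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  if (readBin(hdr[1:4], "integer", 1, 4, endian = "little") != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", 1, 4, endian = "big") != 348L)
      stop("read_nifti: ", path, " is not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_nifti: bad magic '", magic, "' in ", path)
  dims <- grab(40L, "integer", 8L, 2L)
  nd <- dims[1]
  if (nd < 1L || nd > 7L) stop("read_nifti: bad dim[0] = ", nd)
  shape <- dims[2:(1 + nd)]
  datatype <- grab(70L, "integer", 1L, 2L)
  spec <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec))
    stop("read_nifti: unsupported datatype code ", datatype, " in ", path)
  vox_offset <- grab(108L, "double", 1L, 4L)
  scl_slope <- grab(112L, "double", 1L, 4L)
  scl_inter <- grab(116L, "double", 1L, 4L)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n) stop("read_nifti: truncated data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  array(vals, dim = shape)
}
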