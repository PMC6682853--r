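#' Minimal NIfTI-1 volume I/O
#'
#' Lightweight single-file NIfTI-1 (.nii / .nii.gz) reader and writer for the
#' 3-D parametric maps and binary masks this package exchanges. Little-endian
#' only; data types: float32 for maps, uint8 for masks. This is deliberately a
#' small subset of the standard — affine/orientation fields are written as an
#' identity voxel grid because all inputs are assumed co-registered on one grid.
#'
#' @param x 3-D numeric or logical array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param datatype `"float32"` or `"uint8"` (logical input defaults to uint8).
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a 3-D
#'   array (logical when stored as uint8 with only 0/1 values).
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' vol <- array(rnorm(60), c(5, 4, 3))
#' write_nifti(vol, f)
#' max(abs(read_nifti(f) - vol)) < 1e-6
#' @export
write_nifti <- function(x, path, datatype = if (is.logical(x)) "uint8" else "float32") {
  stopifnot(is.array(x), length(dim(x)) == 3)
  datatype <- match.arg(datatype, c("float32", "uint8"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dt_code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wc <- function(s, n) writeBin(c(charToRaw(s), raw(n - length(charToRaw(s)))), con)

  wi(348L, 4)                                  # sizeof_hdr
  wc("", 10); wc("", 18); wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)
  wi(c(3L, dim(x), 1L, 1L, 1L, 1L), 2)         # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                    # intent_p1-3, intent_code
  wi(dt_code, 2); wi(bitpix, 2); wi(0L, 2)     # datatype, bitpix, slice_start
  wf(c(0, 1, 1, 1, 0, 0, 0, 0))                # pixdim[8] (qfac 0, unit voxels)
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1); wi(0L, 1)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)          # cal_max/min, slice_dur, toffset, glmax/min
  wc("", 80); wc("", 24)                       # descrip, aux_file
  wi(c(0L, 0L), 2)                             # qform_code, sform_code
  wf(rep(0, 6))                                # quaternions b,c,d + offsets
  wf(rep(0, 12))                               # srow_x/y/z
  wc("", 16); wc("n+1", 4)                     # intent_name, magic
  writeBin(raw(4), con)                        # extension flag
  if (datatype == "float32") {
    writeBin(as.double(as.vector(x)), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(as.vector(x) != 0), con, size = 1, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", n = 36))
  dims <- ri(8, 2)
  invisible(readBin(con, "raw", n = 14))
  datatype <- ri(1, 2); bitpix <- ri(1, 2); invisible(ri(1, 2))
  invisible(readBin(con, "double", n = 8, size = 4, endian = "little"))
  vox_offset <- readBin(con, "double", n = 1, size = 4, endian = "little")
  # skip the rest of the header + extensions, up to the data offset
  invisible(readBin(con, "raw", n = vox_offset - 112))
  shape <- dims[2:(1 + dims[1])]
  n <- prod(shape)
  vals <- switch(as.character(datatype),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "2"  = readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little"),
    "4"  = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8"  = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  out <- array(vals, dim = shape)
  if (datatype == 2 && all(vals %in% c(0L, 1L))) out <- array(vals == 1L, dim = shape)
  out
}
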