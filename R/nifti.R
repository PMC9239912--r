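#' Minimal NIfTI-1 input/output
#'
#' Self-contained reader and writer for single-file NIfTI-1 images
#' (`.nii` / `.nii.gz`), sufficient for the mask, label and BOLD volumes this
#' package exchanges. Supported on-disk datatypes: uint8, int16, uint16,
#' int32, float32, float64. The voxel-to-world affine is taken from the sform
#' when `sform_code > 0`, else the qform (quaternion), else a pixdim diagonal.
#' `scl_slope` / `scl_inter` scaling is applied on read when meaningful.
#'
#' @param path file path; `.gz` suffix selects gzip compression on write
#'   (reading is transparent either way).
#' @return `read_nifti()` returns a list with `data` (3D or 4D numeric array),
#'   `grid` (a [voxel_grid()] for the spatial dimensions), and `tr` (repetition
#'   time in seconds for 4D images, else `NA`).
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1L):(off + 2L * n)],
                                     "integer", n, 2L, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr_raw[(off + 1L):(off + 4L * n)],
                                     "integer", n, 4L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1L):(off + 4L * n)],
                                     "double", n, 4L, endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "'")
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")

  dim_ <- rd_i16(40L, 8L)
  ndim <- dim_[1L]
  if (ndim < 3L || ndim > 4L)
    stop("only 3D or 4D NIfTI images are supported (ndim = ", ndim, ")")
  shape <- dim_[2:(1L + ndim)]
  datatype <- rd_i16(70L, 1L)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)

  if (sform_code > 0L) {
    affine <- rbind(matrix(rd_f32(280L, 12L), nrow = 3L, byrow = TRUE),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    q <- rd_f32(256L, 6L)  # quatern_b,c,d, qoffset_x,y,z
    b <- q[1]; c_ <- q[2]; d <- q[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2),
      nrow = 3L, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    affine <- rbind(cbind(R %*% S, q[4:6]), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }

  spec <- nifti_dtype_spec(datatype)
  n <- prod(shape)
  gap <- as.integer(round(vox_offset)) - 348L  # header already consumed
  if (gap < 0L) stop("invalid vox_offset in ", path)
  if (gap > 0L) readBin(con, "raw", n = gap)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(as.numeric(vals), dim = shape)
  grid <- voxel_grid(shape[1:3], affine)
  tr <- if (ndim == 4L) pixdim[5] else NA_real_
  list(data = data, grid = grid, tr = tr)
}

nifti_dtype_spec <- function(code) {
  switch(as.character(code),
    "2"   = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
    "4"   = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
    "512" = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L),
    "8"   = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
    "16"  = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
    "64"  = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L),
    stop("unsupported NIfTI datatype code ", code))
}

#' @param data 3D or 4D numeric/logical/integer array.
#' @param grid a [voxel_grid()] for the spatial dimensions.
#' @param datatype on-disk type: "uint8", "int16", "int32", "float32" or
#'   "float64"; `NULL` picks uint8 for logical, int32 for integer and float32
#'   otherwise.
#' @param tr repetition time in seconds, stored in `pixdim[4]` for 4D data.
#' @rdname read_nifti
#' @export
write_nifti <- function(data, grid, path, datatype = NULL, tr = NA_real_) {
  if (is.null(datatype))
    datatype <- if (is.logical(data)) "uint8"
                else if (is.integer(data)) "int32" else "float32"
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype '", datatype, "'"))
  spec <- nifti_dtype_spec(code)
  dims <- dim(data)
  if (length(dims) < 3L || length(dims) > 4L)
    stop("'data' must be a 3D or 4D array")
  if (!identical(as.integer(dims[1:3]), grid$shape))
    stop("data spatial shape does not match grid shape")
  ndim <- length(dims)
  dim8 <- rep(1L, 8L); dim8[1] <- ndim; dim8[2:(1L + ndim)] <- as.integer(dims)
  pixdim <- rep(0, 8L); pixdim[1] <- 1
  pixdim[2:4] <- grid$voxel_size
  if (ndim == 4L) pixdim[5] <- if (is.na(tr)) 0 else tr

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  w_pad <- function(n) writeBin(raw(n), con)

  w_i32(348L)                    # sizeof_hdr
  w_pad(10L); w_pad(18L)         # data_type, db_name
  w_i32(0L); w_i16(0L)           # extents, session_error
  writeBin(charToRaw("r"), con)  # regular
  w_pad(1L)                      # dim_info
  w_i16(dim8)
  w_f32(c(0, 0, 0)); w_i16(0L)   # intent_p1-3, intent_code
  w_i16(code); w_i16(spec$bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  w_f32(pixdim)
  w_f32(352)                     # vox_offset
  w_f32(1); w_f32(0)             # scl_slope, scl_inter
  w_i16(0L); w_pad(1L)           # slice_end, slice_code
  writeBin(as.raw(10L), con)     # xyzt_units: mm | sec
  w_f32(c(0, 0, 0, 0))           # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))               # glmax, glmin
  w_pad(80L); w_pad(24L)         # descrip, aux_file
  w_i16(0L); w_i16(1L)           # qform_code, sform_code
  w_f32(rep(0, 6))               # quatern_b,c,d + qoffset
  w_f32(t(grid$affine[1:3, ]))   # srow_x, srow_y, srow_z
  w_pad(16L)                     # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_pad(4L)                      # extension flag
  vals <- if (spec$what == "integer") as.integer(data) else as.numeric(data)
  writeBin(vals, con, size = spec$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI volume as a binary mask or label volume
#'
#' Convenience wrappers around [read_nifti()]: `read_nifti_mask()` treats any
#' nonzero voxel as set; `read_nifti_labels()` rounds to integer labels.
#'
#' @inheritParams read_nifti
#' @return A [binary_mask()] or [label_volume()].
#' @export
read_nifti_mask <- function(path) {
  x <- read_nifti(path)
  if (length(dim(x$data)) != 3L) stop("expected a 3D volume in ", path)
  binary_mask(x$data != 0, x$grid)
}

#' @rdname read_nifti_mask
#' @export
read_nifti_labels <- function(path) {
  x <- read_nifti(path)
  if (length(dim(x$data)) != 3L) stop("expected a 3D volume in ", path)
  label_volume(round(x$data), x$grid)
}

#' @param mask a [binary_mask()].
#' @rdname read_nifti_mask
#' @export
write_nifti_mask <- function(mask, path)
  write_nifti(mask$data, mask$grid, path, datatype = "uint8")

#' @param labels a [label_volume()].
#' @rdname read_nifti_mask
#' @export
write_nifti_labels <- function(labels, path)
  write_nifti(labels$data, labels$grid, path, datatype = "int32")
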