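#' Count volume container
#'
#' A `count_volume` holds a 3D voxel grid of reconstructed emission counts
#' together with its isotropic voxel size in millimetres. It is the common
#' currency between the synthetic renderer and the quantification routines.
#'
#' @param data numeric 3D array of voxel counts.
#' @param voxel_size isotropic voxel edge length in mm (> 0).
#' @return An object of class `count_volume`.
#' @export
count_volume <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "count_volume")
}

#' @export
print.count_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<count_volume> %d x %d x %d voxels @ %.3g mm, total counts %.4g\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$data)))
  invisible(x)
}

#' @export
dim.count_volume <- function(x) dim(x$data)

# ---- NIfTI-1 IO -------------------------------------------------------------
# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer. The header
# is the fixed 348-byte layout; data are written as float32 in RAS with an
# identity-direction sform scaled by the voxel size. Only what this package
# produces and consumes is supported (3D, common datatypes, no extensions).

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

.nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a count volume as NIfTI-1
#'
#' Writes a single-file NIfTI-1 volume (`.nii`, or gzip-compressed when the
#' path ends in `.gz`), float32 voxel data, RAS orientation, isotropic voxel
#' size in the header `pixdim` and sform.
#'
#' @param volume a [count_volume()].
#' @param path output file path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "count_volume"))
  d <- dim(volume$data)
  vs <- volume$voxel_size
  con <- .nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)

  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }

  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2)             # extents, session_error
  wc("r", 1); wc("", 1)            # regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(16L, 2); wi(32L, 2)           # datatype float32, bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, vs, vs, vs, 0, 0, 0, 0)) # pixdim (qfac = 1)
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1)             # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units: mm
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc("datspectnorm", 80); wc("", 24)
  wi(0L, 2); wi(1L, 2)             # qform_code 0, sform_code 1
  wf(c(0, 0, 0, 0, 0, 0))          # quaternions + qoffsets
  wf(c(vs, 0, 0, 0))               # srow_x
  wf(c(0, vs, 0, 0))               # srow_y
  wf(c(0, 0, vs, 0))               # srow_z
  wc("", 16)                       # intent_name
  wc("n+1", 4)                     # magic
  writeBin(raw(4), con)            # extension flag: none
  writeBin(as.numeric(volume$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file 3D NIfTI-1 volume written by [write_nifti()] (or any
#' NIfTI-1 file using an unscaled common datatype) into a [count_volume()].
#' The voxel size is taken from `pixdim`; anisotropic voxels are rejected.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return A [count_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- .nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path, call. = FALSE)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")

  if (ri(0, 4) != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path,
                             call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path, call. = FALSE)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported",
                           call. = FALSE)

  dims <- ri(40, 2, 8)
  if (dims[1] < 3L) stop("expected a 3D volume, got dim[0] = ", dims[1],
                         call. = FALSE)
  d <- dims[2:4]
  nextra <- if (dims[1] > 3L) prod(pmax(dims[5:(dims[1] + 1L)], 1L)) else 1L
  if (nextra != 1L) stop("only single-frame 3D volumes are supported",
                         call. = FALSE)
  datatype <- ri(70, 2)
  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype,
                          call. = FALSE)
  pixdim <- rf(76, 8)
  vs <- pixdim[2:4]
  if (max(abs(vs - vs[1])) > 1e-5 * vs[1])
    stop("anisotropic voxels are not supported (pixdim = ",
         paste(signif(vs, 4), collapse = " x "), ")", call. = FALSE)
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(d)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) < n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  count_volume(array(vals, dim = d), voxel_size = vs[1])
}
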