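# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, little-endian).
# Only the subset the pipeline needs: 3D volumes, float32/float64/int
# datatypes on read, float32 (or int16 for label grids) on write, spacing in
# pixdim + a diagonal sform. No pre-installed R package in the target stack
# provides NIfTI, so this is implemented here and cross-checked against
# nibabel in the test suite.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol an [image_volume()], a [parcellation()] (label grid is written
#'   as int16), or a bare 3D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing voxel spacing, used when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1)) {
  int_data <- FALSE
  if (inherits(vol, "parcellation")) {
    data <- vol$label_grid
    int_data <- TRUE
  } else if (inherits(vol, "image_volume")) {
    data <- vol$data
    spacing <- vol$spacing
  } else {
    data <- vol
  }
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw(28)                                     # data_type, db_name
  w_i32(0L); w_i16(0L); w_raw(2)                # extents, session_error, regular, dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))               # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent_p1..3, intent_code
  w_i16(if (int_data) 4L else 16L)              # datatype: int16 / float32
  w_i16(if (int_data) 16L else 32L)             # bitpix
  w_i16(0L)                                     # slice_start
  w_f32(c(1, spacing, 0, 0, 0, 0))              # pixdim[8], qfac = 1
  w_f32(352)                                    # vox_offset
  w_f32(c(1, 0))                                # scl_slope, scl_inter
  w_i16(0L); w_raw(1)                           # slice_end, slice_code
  writeBin(as.raw(2L), con)                     # xyzt_units = mm
  w_f32(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw(80); w_raw(24)                          # descrip, aux_file
  w_i16(0L); w_i16(1L)                          # qform_code = 0, sform_code = 1
  w_f32(c(0, 0, 0, 0, 0, 0))                    # quatern b,c,d + qoffset x,y,z
  w_f32(c(spacing[1], 0, 0, 0))                 # srow_x
  w_f32(c(0, spacing[2], 0, 0))                 # srow_y
  w_f32(c(0, 0, spacing[3], 0))                 # srow_z
  w_raw(16)                                     # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  w_raw(1)                                      # magic terminator
  w_raw(4)                                      # extension flag
  if (int_data) w_i16(as.integer(data)) else w_f32(as.numeric(data))
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param space space tag attached to the returned volume.
#' @return an [image_volume()]; integer label volumes come back as numeric
#'   arrays (wrap in [parcellation()] yourself if needed).
#' @export
read_nifti <- function(path, space = "template") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  r_i32 <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer",
                                 size = 4, endian = "little")
  r_i16 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                        size = 2, n = n, endian = "little")
  r_f32 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                        size = 4, n = n, endian = "little")
  if (r_i32(0) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dims <- r_i16(40, 8)
  if (dims[1] < 3) stop("expected a 3D volume: ", path)
  d <- dims[2:4]
  datatype <- r_i16(70)
  pixdim <- r_f32(76, 8)
  vox_offset <- r_f32(108)
  scl_slope <- r_f32(112)
  scl_inter <- r_f32(116)
  skip <- vox_offset - 348
  if (skip > 0) invisible(readBin(con, "raw", n = skip))
  n <- prod(d)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n = n, size = 4, endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(data) < n) stop("truncated NIfTI data: ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  image_volume(array(data, d), spacing = pixdim[2:4], space = space)
}
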