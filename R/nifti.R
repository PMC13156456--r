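# Minimal NIfTI-1 reader/writer for 2D+time stacks.
#
# No NIfTI package is assumed; the format's fixed 348-byte header is
# written directly (little-endian, single-file .nii, magic "n+1", float32
# or float64 data, no scaling). Sufficient for round-tripping the dynamic
# series this package produces and for consuming equivalently simple files
# from other tools.

NIFTI_DT_FLOAT32 <- 16L
NIFTI_DT_FLOAT64 <- 64L

#' Write a 2D+time stack as a NIfTI-1 file
#'
#' Frames `[frame, row, col]` are stored as an `nx = rows`, `ny = cols`,
#' `nz = 1`, `nt = frames` volume (row index fastest), little-endian.
#'
#' @param frames numeric 3D array `[frame, row, col]`.
#' @param path output file, conventionally `.nii`.
#' @param pixdim voxel sizes `(dx, dy, dz, dt)`; default `c(1, 1, 1, 1)`.
#' @param datatype "float32" (default) or "float64".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(frames, path, pixdim = c(1, 1, 1, 1),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  d <- dim(frames)
  dt <- if (datatype == "float32") NIFTI_DT_FLOAT32 else NIFTI_DT_FLOAT64
  bitpix <- if (datatype == "float32") 32L else 64L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4L) writeBin(as.numeric(x), con, size = size,
                                        endian = "little")
  wi(348L, 4L)                       # sizeof_hdr
  writeBin(raw(32L), con)            # data_type[10], db_name[18], extents
  wi(0L, 2L)                         # session_error
  writeBin(as.raw(c(114L, 0L)), con) # regular 'r', dim_info
  wi(c(4L, d[2L], d[3L], 1L, d[1L], 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0))                     # intent_p1..p3
  wi(0L, 2L)                         # intent_code
  wi(dt, 2L); wi(bitpix, 2L); wi(0L, 2L)  # datatype, bitpix, slice_start
  wf(c(0, pixdim, 0, 0, 0))          # pixdim[8] (qfac = 0)
  wf(352)                            # vox_offset
  wf(c(1, 0))                        # scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(2L), con) # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                     # cal_max, cal_min, slice_duration
  wf(0); wi(c(0L, 0L), 4L)           # toffset, glmax, glmin
  writeBin(raw(104L), con)           # descrip[80], aux_file[24]
  wi(c(0L, 0L), 2L)                  # qform_code, sform_code
  wf(rep(0, 18))                     # quatern/qoffset/srow
  writeBin(raw(16L), con)            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  writeBin(raw(4L), con)             # extension flag
  # x fastest: permute [frame,row,col] -> [row,col,frame]
  vals <- as.numeric(aperm(frames, c(2L, 3L, 1L)))
  writeBin(vals, con, size = bitpix %/% 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 2D+time stack written by [write_nifti()]
#'
#' Supports single-file little-endian NIfTI-1 with float32/float64 data
#' and at most one slice; applies `scl_slope`/`scl_inter` when set.
#'
#' @param path `.nii` file.
#' @return Numeric 3D array `[frame, row, col]`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n, size = 4L) readBin(con, "numeric", n = n, size = size,
                                       endian = "little")
  if (ri(1L, 4L) != 348L) stopf("%s: not a little-endian NIfTI-1 file", path)
  readBin(con, "raw", 36L)
  dims <- ri(8L, 2L)
  rf(3L); ri(1L, 2L)
  dt <- ri(1L, 2L); ri(2L, 2L)
  rf(8L)
  vox_offset <- rf(1L)
  scl <- rf(2L)
  if (!dt %in% c(NIFTI_DT_FLOAT32, NIFTI_DT_FLOAT64))
    stopf("%s: unsupported NIfTI datatype %d (only float32/float64)", path, dt)
  nx <- max(dims[2L], 1L); ny <- max(dims[3L], 1L)
  nz <- max(dims[4L], 1L); nt <- max(dims[5L], 1L)
  if (nz != 1L) stopf("%s: expected a single-slice 2D+time stack; nz = %d",
                      path, nz)
  seek(con, vox_offset)
  n <- nx * ny * nz * nt
  vals <- rf(n, size = if (dt == NIFTI_DT_FLOAT32) 4L else 8L)
  if (length(vals) < n) stopf("%s: truncated data section", path)
  if (scl[1L] != 0 && !(scl[1L] == 1 && scl[2L] == 0))
    vals <- vals * scl[1L] + scl[2L]
  aperm(array(vals, c(nx, ny, nt)), c(3L, 1L, 2L))
}

# Run-length encoding of logical masks for the JSON sidecar.
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  list(lengths = as.integer(r$lengths), values = as.logical(r$values),
       dim = dim(mask))
}

rle_to_mask <- function(x) {
  matrix(inverse.rle(list(lengths = as.integer(x$lengths),
                          values = as.logical(x$values))),
         x$dim[1L], x$dim[2L])
}
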