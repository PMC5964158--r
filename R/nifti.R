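# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what the pipeline needs: 3D volumes, float32/float64/int16/uint8/int32
# data, sform affine (sform_code = 1, 0-based voxel indices, RAS mm). No
# neuroimaging package is assumed; round-trip fidelity is tested against an
# independent reference implementation.

nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param vol an `intensity_volume`, `labeled_volume`, or a plain 3D array
#'   (then `affine` must be given).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix; taken from `vol` when omitted.
#' @param datatype `"float32"`, `"float64"`, `"int16"`, `"int32"` or `"uint8"`.
#' @export
write_nifti <- function(vol, path, affine = NULL,
                        datatype = c("float32", "int16", "uint8", "int32", "float64")) {
  datatype <- match.arg(datatype)
  if (inherits(vol, "intensity_volume")) { a <- vol$values; affine <- vol$affine }
  else if (inherits(vol, "labeled_volume")) {
    a <- vol$labels; affine <- vol$affine
    if (missing(datatype)) datatype <- "int16"
  } else a <- vol
  if (is.null(affine)) stop_repe("affine required for plain arrays", "repe_input_error")
  if (is.logical(a)) { storage.mode(a) <- "integer"; if (missing(datatype)) datatype <- "uint8" }
  d <- dim(a)
  stopifnot(length(d) == 3L)
  code <- c(float32 = 16L, int16 = 4L, uint8 = 2L, int32 = 8L, float64 = 64L)[[datatype]]
  dtrow <- nifti_datatypes[nifti_datatypes$code == code, ]
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L)                       # sizeof_hdr
  wc("", 10); wc("", 18)         # data_type, db_name (unused)
  wi(0L); wi(0L, 2L); wc("r", 1) # extents, session_error, regular
  writeBin(as.raw(0L), con)      # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)   # dim[8]
  wf(c(0, 0, 0))                 # intent_p1..p3
  wi(0L, 2L)                     # intent_code
  wi(code, 2L)                   # datatype
  wi(8L * dtrow$size, 2L)        # bitpix
  wi(0L, 2L)                     # slice_start
  wf(c(1, vox, 1, 1, 1, 1))      # pixdim[8] (qfac = 1)
  wf(352)                        # vox_offset
  wf(1); wf(0)                   # scl_slope, scl_inter
  wi(0L, 2L); writeBin(as.raw(c(0L, 0L)), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L))                  # glmax, glmin
  wc("", 80); wc("", 24)         # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)         # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))        # quatern b,c,d, qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x, srow_y, srow_z
  wc("", 16); wc("n+1", 4)       # intent_name, magic
  writeBin(as.raw(c(0, 0, 0, 0)), con)  # extension flag
  writeBin(if (dtrow$what == "double") as.double(a) else as.integer(a),
           con, size = dtrow$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array), `affine` (4x4) and `datatype_code`.
#' @export
read_nifti <- function(path) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  ri <- function(n, size = 4L, signed = TRUE)
    readBin(con, "integer", n = n, size = size, endian = "little", signed = signed)
  rf <- function(n) readBin(con, "double", n = n, size = 4L, endian = "little")
  hdr_size <- ri(1)
  if (!identical(hdr_size, 348L)) stop_repe("not a NIfTI-1 file", "repe_io_error")
  readBin(con, "raw", n = 36)            # up to dim[]
  dim8 <- ri(8, 2L)
  rf(3); ri(1, 2L)
  datatype <- ri(1, 2L)
  ri(1, 2L); ri(1, 2L)                    # bitpix, slice_start
  rf(8)                                   # pixdim
  vox_offset <- rf(1)
  rf(2)                                   # scl
  readBin(con, "raw", n = 2 + 1 + 1)
  rf(4); ri(2)
  readBin(con, "raw", n = 104)            # descrip + aux_file
  ri(1, 2L); sform_code <- ri(1, 2L)
  rf(6)
  srow <- rbind(rf(4), rf(4), rf(4))
  readBin(con, "raw", n = 20)             # intent_name + magic
  readBin(con, "raw", n = vox_offset - 348)
  dtrow <- nifti_datatypes[nifti_datatypes$code == datatype, ]
  if (nrow(dtrow) == 0) stop_repe("unsupported NIfTI datatype", "repe_io_error")
  d <- dim8[2:(1 + dim8[1])]
  if (length(d) < 3) d <- c(d, rep(1L, 3 - length(d)))
  n <- prod(d)
  data <- readBin(con, dtrow$what, n = n, size = dtrow$size,
                  endian = "little", signed = dtrow$signed)
  affine <- rbind(srow, c(0, 0, 0, 1))
  list(data = array(data, d), affine = affine, datatype_code = datatype,
       sform_code = sform_code)
}
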