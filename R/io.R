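# Minimal NIfTI-1 codec.
#
# No NIfTI package is available in the supported environment, so the pipeline
# carries its own small reader/writer for the files it emits: single-file
# .nii / .nii.gz, datatypes int16/int32/float32/float64, identity scaling,
# little- or big-endian on read (always little-endian on write), no
# qform/sform rotation (axis-aligned grids only). Voxel size lives in
# pixdim[2:4] (mm) and the repetition time in pixdim[5] (s), the standard
# slots, so files round-trip through nibabel/AFNI-style tools.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti <- function(data, path, voxel_size_mm, tr_s = 0) {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L))
  integerish <- is.integer(data)
  datatype <- if (integerish) 8L else 64L   # DT_INT32 / DT_FLOAT64
  bitpix <- if (integerish) 32L else 64L
  nd <- length(dim(data))
  dims <- c(nd, dim(data), rep(1L, 7L - nd))
  pixdim <- c(1, voxel_size_mm, tr_s, 0, 0, 0)

  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                      # sizeof_hdr
  wc(10 + 18 + 4 + 2 + 1 + 1)      # data_type..dim_info (unused)
  wi(dims, 2)                      # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1-3, intent_code
  wi(datatype, 2); wi(bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(pixdim)                       # pixdim[8]
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wc(1)                 # slice_end, slice_code
  writeBin(as.raw(10L), con)       # xyzt_units: NIFTI_UNITS_MM | SEC
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc(80 + 24)                      # descrip, aux_file
  wi(c(0L, 0L), 2)                 # qform_code, sform_code
  wf(rep(0, 6))                    # quatern_b,c,d, qoffset_x,y,z
  wf(rep(0, 12))                   # srow_x, srow_y, srow_z
  wc(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wc(4)                            # extension flag
  if (integerish) {
    writeBin(as.vector(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.vector(as.double(data)), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("malformed NIfTI header: file too short")
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("malformed NIfTI header: sizeof_hdr != 348")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI header: bad magic")
  rd_i2 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                    n = n, size = 2, endian = endian)
  rd_f4 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                    n = n, size = 4, endian = endian)
  dims <- rd_i2(40, 8)
  nd <- dims[1]
  if (nd < 3 || nd > 4) stop("only 3D/4D NIfTI volumes are supported")
  shape <- dims[2:(1 + nd)]
  datatype <- rd_i2(70, 1)
  pixdim <- rd_f4(76, 8)
  vox_offset <- rd_f4(108, 1)
  scl_slope <- rd_f4(112, 1)
  scl_inter <- rd_f4(116, 1)
  if (!(scl_slope %in% c(0, 1)) || scl_inter != 0)
    stop("scaled NIfTI data (scl_slope/scl_inter) not supported")
  nvox <- prod(shape)
  seek_skip <- vox_offset - 348
  if (seek_skip > 0) readBin(con, "raw", n = seek_skip)
  vals <- switch(as.character(datatype),
    "4"  = readBin(con, "integer", n = nvox, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n = nvox, size = 4, endian = endian),
    "16" = readBin(con, "double", n = nvox, size = 4, endian = endian),
    "64" = readBin(con, "double", n = nvox, size = 8, endian = endian),
    stop(sprintf("unsupported NIfTI datatype %d", datatype)))
  if (length(vals) < nvox) stop("malformed NIfTI: truncated voxel data")
  list(data = array(vals, dim = shape),
       voxel_size_mm = pixdim[2:4],
       tr_s = pixdim[5])
}

#' Read a BOLD or atlas volume from NIfTI-1
#'
#' Reads a single-file NIfTI-1 volume (.nii or .nii.gz). 4D files become
#' [bold4d] objects (TR taken from pixdim\[5\]); 3D integer files become
#' [atlas_volume] objects, for which a label table must be supplied.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param what `"bold"` (requires 4D), `"atlas"` (requires 3D integer), or
#'   `"auto"` (by dimensionality).
#' @param label_table named integer vector (ROI name -> label), needed when
#'   reading an atlas.
#' @return a [bold4d] or [atlas_volume].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, what = c("auto", "bold", "atlas"),
                        label_table = NULL) {
  what <- match.arg(what)
  v <- read_nifti(path)
  nd <- length(dim(v$data))
  if (what == "auto") what <- if (nd == 4L) "bold" else "atlas"
  if (what == "bold") {
    if (nd != 4L) stop(sprintf("'%s' is %dD; a BOLD volume must be 4D",
                               path, nd))
    if (v$tr_s <= 0) stop("BOLD NIfTI missing TR in pixdim[5]")
    bold4d(v$data, tr_s = v$tr_s, voxel_size_mm = v$voxel_size_mm)
  } else {
    if (nd != 3L) stop(sprintf("'%s' is %dD; an atlas must be 3D", path, nd))
    if (any(v$data != round(v$data)))
      stop("atlas volume must contain integer labels")
    storage.mode(v$data) <- "integer"
    if (is.null(label_table)) {
      labs <- sort(unique(as.integer(v$data[v$data > 0])))
      label_table <- setNames(labs, paste0("roi", labs))
    }
    atlas_volume(v$data, voxel_size_mm = v$voxel_size_mm,
                 label_table = label_table)
  }
}

#' Write a BOLD or atlas volume as NIfTI-1
#'
#' Lossless round trip: BOLD data are stored as float64 with the TR in
#' pixdim\[5\]; atlas labels as int32. `.gz` suffixes are honoured.
#'
#' @param obj a [bold4d] or [atlas_volume].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, "bold4d")) {
    write_nifti(obj$data, path, obj$voxel_size_mm, tr_s = obj$tr_s)
  } else if (inherits(obj, "atlas_volume")) {
    write_nifti(obj$labels, path, obj$voxel_size_mm, tr_s = 0)
  } else stop("`obj` must be a bold4d or atlas_volume")
  invisible(path)
}

#' Read a physiological or accelerometer trace
#'
#' Traces are 2-column delimited text (time_s, value) with one header line —
#' the interchange format for heart-rate and accelerometer recordings. Time
#' must be strictly increasing.
#'
#' @param path path to the delimited file.
#' @param sep field separator (default comma).
#' @return data.frame with numeric columns `time_s`, `value`.
#' @export
read_trace <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep,
                   colClasses = c("numeric", "numeric"))
  if (ncol(df) != 2L) stop("trace file must have exactly 2 columns")
  names(df) <- c("time_s", "value")
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$value)))
    stop("trace contains non-numeric or non-finite rows")
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("trace time column must be strictly increasing")
  df
}

#' @rdname read_trace
#' @param trace data.frame with columns `time_s`, `value`.
#' @export
write_trace <- function(trace, path, sep = ",") {
  stopifnot(all(c("time_s", "value") %in% names(trace)))
  write.table(trace[c("time_s", "value")], path, sep = sep,
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
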