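#' 4D BOLD image container
#'
#' Light S3 wrapper pairing a 4D array (x, y, z, time) with its repetition
#' time and voxel size — the unit of fMRI analysis throughout the package.
#'
#' @param data numeric 4D array, dimensions (x, y, z, volumes).
#' @param tr_s repetition time in seconds (> 0).
#' @param voxel_size_mm length-3 numeric voxel size in mm.
#' @return an object of class `bold4d` with elements `data`, `tr_s`,
#'   `voxel_size_mm`.
#' @export
bold4d <- function(data, tr_s, voxel_size_mm = c(1.7, 1.7, 2.4)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, time)")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("`tr_s` must be a single positive number")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive numbers")
  structure(list(data = data, tr_s = as.double(tr_s),
                 voxel_size_mm = as.double(voxel_size_mm)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d volumes, TR %g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], x$tr_s,
              paste(signif(x$voxel_size_mm, 3), collapse = " x ")))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

n_volumes <- function(bold) dim(bold$data)[4L]

volume_onsets <- function(bold) (seq_len(n_volumes(bold)) - 1) * bold$tr_s

#' 3D ROI label volume
#'
#' Integer label image mapping voxels to named regions of interest; label 0 is
#' background and every nonzero label must be named in `label_table`.
#'
#' @param labels integer 3D array of ROI labels (0 = background).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param label_table named integer vector, ROI name -> label.
#' @return an object of class `atlas_volume`.
#' @seealso [make_atlas()] for the synthetic block-ROI constructor.
#' @export
atlas_volume <- function(labels, voxel_size_mm = c(1.7, 1.7, 2.4),
                         label_table) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (any(labels < 0)) stop("labels must be >= 0 (0 = background)")
  if (is.null(names(label_table)) || any(!nzchar(names(label_table))))
    stop("`label_table` must be a named integer vector (ROI name -> label)")
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (!all(present %in% label_table))
    stop("every nonzero label in the volume must appear in `label_table`")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size_mm = as.double(voxel_size_mm),
                 label_table = setNames(as.integer(label_table),
                                        names(label_table))),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<atlas_volume> %d x %d x %d, %d ROIs: %s\n",
              d[1], d[2], d[3], length(x$label_table),
              paste(names(x$label_table), collapse = ", ")))
  invisible(x)
}

# logical mask of an ROI by name
roi_mask <- function(atlas, roi) {
  if (!roi %in% names(atlas$label_table))
    stop(sprintf("ROI '%s' not in atlas", roi))
  atlas$labels == atlas$label_table[[roi]]
}

#' Accelerometer trace container
#'
#' Uniformly sampled single-channel acceleration magnitude with the session
#' event times needed for tremor scoring.
#'
#' @param samples numeric vector of acceleration values.
#' @param rate_hz sampling rate (100 Hz in the motivating protocol).
#' @param t0_s time of the first sample, seconds.
#' @param events list with `baseline_start_s`, `injection_s`, `end_s`
#'   (ordered).
#' @return an object of class `accel_trace`.
#' @export
accel_trace <- function(samples, rate_hz, t0_s = 0,
                        events = list(baseline_start_s = t0_s,
                                      injection_s = NA_real_,
                                      end_s = t0_s + length(samples) / rate_hz)) {
  if (rate_hz <= 0) stop("`rate_hz` must be positive")
  if (!all(is.finite(samples))) stop("samples must be finite")
  ev <- c(events$baseline_start_s, events$injection_s, events$end_s)
  if (!any(is.na(ev)) && is.unsorted(ev))
    stop("events must be ordered: baseline_start <= injection <= end")
  structure(list(samples = as.double(samples), rate_hz = as.double(rate_hz),
                 t0_s = as.double(t0_s), events = events),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.1f s), injection at %s s\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              format(x$events$injection_s)))
  invisible(x)
}

#' Statistical map container
#'
#' A 3D map of per-voxel statistics with its kind and degrees of freedom.
#' `degenerate` marks voxels whose residual variance was (numerically) zero:
#' their t is reported as 0 rather than infinite.
#'
#' @param values numeric 3D array.
#' @param kind one of `"beta"`, `"t"`, `"p"`, `"psc"`, `"slope"`.
#' @param df degrees of freedom (required for t maps).
#' @param degenerate optional logical 3D array flagging zero-variance voxels.
#' @param threshold optional named list of threshold metadata.
#' @return an object of class `stat_map`.
#' @export
stat_map <- function(values, kind = c("beta", "t", "p", "psc", "slope"),
                     df = NA_integer_, degenerate = NULL, threshold = NULL) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (kind == "t" && (is.na(df) || df < 1)) stop("t maps need df >= 1")
  if (kind == "p" && (min(values) < 0 || max(values) > 1))
    stop("p maps must lie in [0, 1]")
  structure(list(values = values, kind = kind, df = df,
                 degenerate = degenerate, threshold = threshold),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stat_map:%s> %d x %d x %d, df = %s, range [%.4g, %.4g]\n",
              x$kind, d[1], d[2], d[3], format(x$df),
              min(x$values), max(x$values)))
  invisible(x)
}

#' ROI-mean time-series container
#'
#' @param values numeric matrix, one row per named ROI, one column per volume.
#' @param tr_s repetition time, seconds.
#' @return an object of class `roi_series`.
#' @seealso [roi_mean_series()]
#' @export
roi_series <- function(values, tr_s) {
  if (!is.matrix(values) || is.null(rownames(values)))
    stop("`values` must be a matrix with ROI names as rownames")
  if (any(!is.finite(values))) stop("ROI series must be finite")
  structure(list(values = values, tr_s = as.double(tr_s)),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> %d ROIs x %d volumes (TR %g s): %s\n",
              nrow(x$values), ncol(x$values), x$tr_s,
              paste(rownames(x$values), collapse = ", ")))
  invisible(x)
}

check_congruent <- function(bold, atlas) {
  if (!identical(dim(bold$data)[1:3], dim(atlas$labels)))
    stop("BOLD grid and atlas grid do not match")
  invisible(TRUE)
}
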