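#' Resample a physiological trace to volume onsets
#'
#' Linearly interpolates a continuously recorded trace (e.g. heart rate) at
#' the fMRI volume onset times 0, TR, 2 TR, ..., then mean-centres and scales
#' it to unit variance so it can enter a design matrix as a nuisance
#' regressor.
#'
#' @param trace data.frame with columns `time_s`, `value` covering the whole
#'   scan interval.
#' @param n_volumes number of volumes.
#' @param tr_s repetition time, seconds.
#' @param center,scale whether to mean-centre / unit-variance scale the
#'   resampled regressor (both default TRUE; the raw interpolated values are
#'   returned when both are FALSE).
#' @return numeric vector of length `n_volumes`.
#' @export
resample_to_volumes <- function(trace, n_volumes, tr_s,
                                center = TRUE, scale = TRUE) {
  if (nrow(trace) < 2) stop("trace must contain at least 2 points")
  onsets <- (seq_len(n_volumes) - 1) * tr_s
  if (min(trace$time_s) > min(onsets) || max(trace$time_s) < max(onsets))
    stop("trace does not cover the scan interval")
  x <- approx(trace$time_s, trace$value, xout = onsets)$y
  if (center) x <- x - mean(x)
  if (scale) {
    s <- sd(x)
    if (s == 0)
      stop("degenerate regressor: trace is constant over the scan")
    x <- x / s
  }
  x
}

#' Assemble a nuisance design matrix
#'
#' Columns: intercept, centred linear drift, and the (centred, scaled)
#' heart-rate regressor, optionally lagged by an integer number of volumes.
#' The recorded BOLD drift lags the cardiac response slightly, but the
#' published analysis uses the waveform directly, so the default lag is 0.
#'
#' @param hr_regressor per-volume heart-rate regressor (from
#'   [resample_to_volumes()]).
#' @param drift include a linear drift column (default TRUE).
#' @param lag_volumes integer lag applied to the heart-rate column; positive
#'   values shift the waveform later (edge values are held).
#' @return numeric matrix with labelled columns, full column rank.
#' @export
nuisance_design <- function(hr_regressor, drift = TRUE, lag_volumes = 0L) {
  n <- length(hr_regressor)
  hr <- hr_regressor
  if (lag_volumes != 0) {
    idx <- pmin(pmax(seq_len(n) - lag_volumes, 1L), n)
    hr <- hr[idx]
    hr <- hr - mean(hr)
  }
  cols <- list(intercept = rep(1, n))
  if (drift) {
    dr <- seq_len(n) - (n + 1) / 2
    cols$drift <- dr / sd(dr)
  }
  cols$heart_rate <- hr
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X)) stop("nuisance design is rank deficient")
  X
}

#' Remove nuisance signal from a BOLD series by voxelwise OLS
#'
#' Per voxel, ordinary least squares of the series on the design; the
#' residual is the series minus the fit, with the intercept column's
#' contribution re-added so the residual keeps its mean level (required for
#' downstream percent-signal-change). Regressing the residual on the same
#' design again changes nothing, and residuals are exactly orthogonal to
#' every centred non-intercept column.
#'
#' @param bold a [bold4d].
#' @param design nuisance design matrix (see [nuisance_design()]); must have
#'   as many rows as volumes and full column rank. A column named
#'   `intercept` (or a constant column) is re-added to the residual.
#' @return list with `residual` and `fitted` [bold4d] objects (`fitted` is
#'   the removed artifact, mean level excluded).
#' @export
regress_nuisance <- function(bold, design) {
  X <- as.matrix(design)
  n <- n_volumes(bold)
  if (nrow(X) != n) stop("design rows must equal the number of volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("nuisance design is rank deficient")
  Y <- matrix(bold$data, nrow = prod(dim(bold$data)[1:3]), ncol = n)
  if (any(!is.finite(Y))) stop("voxel series must be finite")
  Y <- t(Y) # volumes x voxels
  beta <- qr.coef(qrX, Y)
  intercept_col <- which(colnames(X) == "intercept")
  if (length(intercept_col) == 0)
    intercept_col <- which(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))
  keep <- setdiff(seq_len(ncol(X)), intercept_col[1])
  # Y - (non-intercept fit) = OLS residual + intercept contribution,
  # i.e. the cleaned series with its mean level retained
  fitted_nuis <- X[, keep, drop = FALSE] %*% beta[keep, , drop = FALSE]
  resid <- Y - fitted_nuis
  d <- dim(bold$data)
  list(residual = bold4d(array(t(resid), dim = d), tr_s = bold$tr_s,
                         voxel_size_mm = bold$voxel_size_mm),
       fitted = bold4d(array(t(fitted_nuis), dim = d), tr_s = bold$tr_s,
                       voxel_size_mm = bold$voxel_size_mm))
}
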