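#' Hann-windowed amplitude spectrum of one analysis bin
#'
#' Single-sided amplitude spectrum of a 10-s accelerometer bin: the segment
#' is Hann-windowed and Fourier-transformed; amplitudes are scaled by the
#' window's coherent gain (2 |X_k| / sum(w) for k > 0, |X_0| / sum(w) at
#' DC), so a unit-amplitude sinusoid centred on a bin reports amplitude 1.
#' Frequency resolution is 1 / bin width (0.1 Hz for 10-s bins).
#'
#' @param segment numeric vector of exactly `bin_width_s * rate_hz` samples.
#' @param rate_hz sampling rate, Hz.
#' @param bin_width_s analysis bin width, s (default 10).
#' @return data.frame with columns `freq_hz`, `amplitude` (single-sided,
#'   frequencies 0 to Nyquist).
#' @export
window_spectrum <- function(segment, rate_hz, bin_width_s = 10) {
  n_expect <- round(bin_width_s * rate_hz)
  n <- length(segment)
  if (n != n_expect)
    stop(sprintf("segment must contain exactly %d samples (%g s at %g Hz)",
                 n_expect, bin_width_s, rate_hz))
  w <- hann_window(n)
  X <- fft(segment * w)
  half <- floor(n / 2)
  k <- 0:half
  amp <- Mod(X[k + 1]) / sum(w)
  amp[k > 0 & k < n - half] <- 2 * amp[k > 0 & k < n - half]
  data.frame(freq_hz = k * rate_hz / n, amplitude = amp)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

#' Mean spectral amplitude within a frequency band
#'
#' Mean of the amplitudes at bins with f_lo <= f < f_hi (half-open, so the
#' 10 Hz bin belongs to the tremor band, resolving the overlap between the
#' "0-10 Hz" motion band and the "10-16 Hz" tremor band). The DC bin is
#' excluded when f_lo = 0: a constant offset is gravity, not motion.
#'
#' @param spectrum data.frame from [window_spectrum()].
#' @param f_lo_hz,f_hi_hz band edges, Hz; f_lo < f_hi <= Nyquist.
#' @return mean amplitude over the band's bins.
#' @export
band_mean <- function(spectrum, f_lo_hz, f_hi_hz) {
  if (f_lo_hz >= f_hi_hz) stop("band edges must satisfy f_lo < f_hi")
  if (f_hi_hz > max(spectrum$freq_hz) + 1e-9)
    stop("band extends beyond the Nyquist frequency")
  sel <- spectrum$freq_hz >= f_lo_hz - 1e-9 &
    spectrum$freq_hz < f_hi_hz - 1e-9
  if (f_lo_hz == 0) sel <- sel & spectrum$freq_hz > 1e-9
  if (!any(sel)) stop("no spectral bins inside the band")
  mean(spectrum$amplitude[sel])
}

#' Per-bin tremor index of an accelerometer trace
#'
#' The trace is cut into consecutive non-overlapping bins (10 s by default,
#' aligned to the baseline start); each bin's tremor index is the mean
#' amplitude in the tremor band (10-16 Hz) divided by the mean amplitude of
#' the non-tremor motion band (0-10 Hz). The ratio is dimensionless and
#' invariant to rescaling the trace. Bins whose motion-band mean is zero
#' (silent signal) are flagged undefined (NA).
#'
#' @param trace an [accel_trace].
#' @param bin_width_s analysis bin width, s (default 10).
#' @param tremor_band,motion_band numeric length-2 band edges, Hz.
#' @param use_power use mean squared amplitude instead of amplitude in both
#'   bands (default FALSE: amplitude-spectrum ratio).
#' @return object of class `tremor_index_series`: data.frame-like list with
#'   `bin_start_s`, `index`, plus `bin_width_s`, `normalized = FALSE`.
#' @export
tremor_index_series <- function(trace, bin_width_s = 10,
                                tremor_band = c(10, 16),
                                motion_band = c(0, 10),
                                use_power = FALSE) {
  fs <- trace$rate_hz
  nper <- round(bin_width_s * fs)
  nbins <- floor(length(trace$samples) / nper)
  if (nbins < 1) stop("trace shorter than one analysis bin")
  idx <- numeric(nbins)
  starts <- trace$t0_s + (seq_len(nbins) - 1) * bin_width_s
  for (b in seq_len(nbins)) {
    seg <- trace$samples[((b - 1) * nper + 1):(b * nper)]
    spec <- window_spectrum(seg, fs, bin_width_s)
    if (use_power) spec$amplitude <- spec$amplitude^2
    m1 <- band_mean(spec, motion_band[1], motion_band[2])
    m2 <- band_mean(spec, tremor_band[1], tremor_band[2])
    idx[b] <- if (m1 == 0) NA_real_ else m2 / m1
  }
  structure(list(bin_start_s = starts, index = idx,
                 bin_width_s = bin_width_s, normalized = FALSE,
                 baseline_mean = NA_real_, events = trace$events),
            class = "tremor_index_series")
}

#' @export
print.tremor_index_series <- function(x, ...) {
  cat(sprintf("<tremor_index_series> %d bins of %g s%s, index range [%.3g, %.3g]\n",
              length(x$index), x$bin_width_s,
              if (x$normalized) " (baseline-normalized)" else "",
              min(x$index, na.rm = TRUE), max(x$index, na.rm = TRUE)))
  invisible(x)
}

#' Aggregate tremor indices into windows and normalise to baseline
#'
#' Averages the per-bin indices over consecutive aggregation windows (10 min
#' by default) and divides every window by the mean per-bin index inside the
#' baseline period (the 30 min before injection in the published protocol),
#' so a stationary signal sits at 1.
#'
#' @param series a `tremor_index_series` from [tremor_index_series()].
#' @param baseline_window numeric length-2, start/end of the baseline in
#'   trace time, s; must precede the injection when one is recorded.
#' @param window_s aggregation window, s (default 600 = 10 min).
#' @return a normalised `tremor_index_series` with `bin_width_s = window_s`,
#'   `normalized = TRUE` and the `baseline_mean` used.
#' @export
aggregate_and_normalize <- function(series, baseline_window,
                                    window_s = 600) {
  if (series$normalized) stop("series is already normalized")
  bs <- series$bin_start_s
  base_sel <- bs >= baseline_window[1] & bs + series$bin_width_s <=
    baseline_window[2] + 1e-9
  if (!any(base_sel)) stop("baseline window contains no bins")
  inj <- series$events$injection_s
  if (!is.null(inj) && !is.na(inj) && baseline_window[2] > inj + 1e-9)
    stop("baseline window must be pre-injection")
  baseline_mean <- mean(series$index[base_sel], na.rm = TRUE)
  win_id <- floor((bs - bs[1]) / window_s)
  starts <- bs[1] + sort(unique(win_id)) * window_s
  agg <- tapply(series$index, win_id, mean, na.rm = TRUE)
  structure(list(bin_start_s = as.numeric(starts),
                 index = as.numeric(agg) / baseline_mean,
                 bin_width_s = window_s, normalized = TRUE,
                 baseline_mean = baseline_mean,
                 baseline_window = baseline_window,
                 events = series$events),
            class = "tremor_index_series")
}

#' Maximum post-injection tremor index
#'
#' The maximum normalised aggregated index over windows starting at or
#' after the injection — the per-session tremor severity summary whose
#' decline across sessions quantifies tolerance.
#'
#' @param series a normalised `tremor_index_series`.
#' @param post_window optional numeric length-2 restricting the search, s;
#'   default from injection time to the end.
#' @return the maximum normalised index (scalar).
#' @export
max_tremor_index <- function(series, post_window = NULL) {
  if (!series$normalized) stop("series must be baseline-normalized")
  inj <- series$events$injection_s
  if (is.null(post_window))
    post_window <- c(if (is.null(inj) || is.na(inj)) -Inf else inj, Inf)
  sel <- series$bin_start_s + series$bin_width_s > post_window[1] &
    series$bin_start_s < post_window[2]
  vals <- series$index[sel]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no defined values in the post window")
  max(vals)
}

#' Tremor duration from a normalised index series
#'
#' The published work reports tremor duration without defining its
#' criterion; the package's stand-in rule calls a post-injection window
#' tremulous when its normalised value exceeds baseline mean + k * baseline
#' SD (computed on the normalised windows inside the baseline period), and
#' returns the length of the longest contiguous suprathreshold run.
#'
#' @param series a normalised `tremor_index_series` (from
#'   [aggregate_and_normalize()], which stores the baseline window).
#' @param k threshold multiplier on the baseline SD (default 2).
#' @return duration in seconds (0 when never suprathreshold).
#' @export
tremor_duration <- function(series, k = 2) {
  if (!series$normalized) stop("series must be baseline-normalized")
  if (is.null(series$baseline_window))
    stop("series carries no baseline statistics")
  bw <- series$baseline_window
  base_sel <- series$bin_start_s >= bw[1] &
    series$bin_start_s + series$bin_width_s <= bw[2] + 1e-9
  base_vals <- series$index[base_sel]
  if (length(base_vals) == 0) stop("series carries no baseline statistics")
  thr <- mean(base_vals) + k * if (length(base_vals) > 1) sd(base_vals) else 0
  inj <- series$events$injection_s
  post <- series$bin_start_s + series$bin_width_s >
    (if (is.null(inj) || is.na(inj)) bw[2] else inj)
  supra <- post & !is.na(series$index) & series$index > thr
  if (!any(supra)) return(0)
  runs <- rle(supra)
  max(runs$lengths[runs$values]) * series$bin_width_s
}

#' Across-session tremor trend statistics
#'
#' Pairwise paired t-tests on the per-animal maximum tremor indices for
#' every session pair, and a one-way ANOVA on tremor durations with session
#' as the factor — the tolerance statistics reported for repeated drug
#' administration. Degenerate variance (identical differences) is flagged
#' rather than producing infinite t.
#'
#' @param max_indices numeric matrix, animals x sessions, of maximum tremor
#'   indices.
#' @param durations numeric matrix, animals x sessions, of tremor durations
#'   (seconds); defaults to `max_indices` being the only input when absent.
#' @return list with `pairwise` (data.frame session_a, session_b, t, df, p,
#'   degenerate) and `anova` (list F, df1, df2, p) on durations.
#' @export
session_trend_stats <- function(max_indices, durations = NULL) {
  M <- as.matrix(max_indices)
  if (ncol(M) < 2) stop("need at least 2 sessions")
  if (nrow(M) < 2) stop("need at least 2 animals")
  pairs <- utils::combn(ncol(M), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dif <- M[, a] - M[, b]
    n <- length(dif)
    s <- sd(dif)
    degenerate <- s == 0
    tval <- if (degenerate) NA_real_ else mean(dif) / (s / sqrt(n))
    pval <- if (degenerate) NA_real_ else 2 * pt(-abs(tval), df = n - 1)
    data.frame(session_a = a, session_b = b, t = tval, df = n - 1, p = pval,
               degenerate = degenerate)
  })
  pairwise <- do.call(rbind, rows)

  D <- if (is.null(durations)) M else as.matrix(durations)
  grp <- factor(rep(seq_len(ncol(D)), each = nrow(D)))
  vals <- as.vector(D)
  mu <- mean(vals)
  ss_between <- sum(tapply(vals, grp, length) *
                      (tapply(vals, grp, mean) - mu)^2)
  ss_within <- sum((vals - ave(vals, grp))^2)
  df1 <- nlevels(grp) - 1
  df2 <- length(vals) - nlevels(grp)
  if (ss_within == 0) {
    anova_out <- list(F = if (ss_between == 0) 0 else Inf, df1 = df1,
                      df2 = df2, p = NA_real_, degenerate = TRUE)
  } else {
    Fv <- (ss_between / df1) / (ss_within / df2)
    anova_out <- list(F = Fv, df1 = df1, df2 = df2,
                      p = pf(Fv, df1, df2, lower.tail = FALSE),
                      degenerate = FALSE)
  }
  list(pairwise = pairwise, anova = anova_out)
}
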