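#' Canonical double-gamma hemodynamic response function
#'
#' The impulse response linking neural events to BOLD: a gamma-shaped main
#' lobe minus a scaled, later gamma undershoot. Defaults are the
#' human-canonical parameters (peak delay 5 s, undershoot delay 15 s,
#' undershoot ratio 1/6, unit dispersion); the pig HRF has not been
#' characterised, so these are exposed for adjustment. The response is 0 for
#' t <= 0 and is peak-normalised to 1 inside [build_design()].
#'
#' @param t time in seconds (vectorised).
#' @param params list from [hrf_params()].
#' @return response values, same length as `t`.
#' @export
hrf <- function(t, params = hrf_params()) {
  with(params, {
    if (peak_delay_s <= 0 || undershoot_delay_s <= 0 || dispersion_s <= 0 ||
        undershoot_dispersion_s <= 0)
      stop("HRF delays and dispersions must be positive")
    a1 <- peak_delay_s / dispersion_s + 1
    a2 <- undershoot_delay_s / undershoot_dispersion_s + 1
    h <- dgamma(t, shape = a1, scale = dispersion_s) -
      ratio * dgamma(t, shape = a2, scale = undershoot_dispersion_s)
    h[t <= 0] <- 0
    h
  })
}

#' @rdname hrf
#' @param peak_delay_s mode of the main lobe, s.
#' @param undershoot_delay_s mode of the undershoot lobe, s.
#' @param ratio undershoot amplitude relative to the main lobe.
#' @param dispersion_s,undershoot_dispersion_s gamma scale parameters, s.
#' @export
hrf_params <- function(peak_delay_s = 5, undershoot_delay_s = 15,
                       ratio = 1 / 6, dispersion_s = 1,
                       undershoot_dispersion_s = 1) {
  list(peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
       ratio = ratio, dispersion_s = dispersion_s,
       undershoot_dispersion_s = undershoot_dispersion_s)
}

# HRF-convolved injection-block regressor sampled at volume onsets,
# peak-normalised to 1. `hrf_params = NULL` means a unit impulse (the
# regressor is then the boxcar itself).
task_regressor <- function(n_volumes, tr_s, onset_s, block_length_s,
                           hrf_params = phtremor::hrf_params(), dt = 0.1) {
  scan_s <- n_volumes * tr_s
  if (block_length_s <= 0) stop("block length must be positive")
  if (onset_s < 0 || onset_s + block_length_s > scan_s)
    stop("injection block must lie within the scan")
  onsets <- (seq_len(n_volumes) - 1) * tr_s
  box <- as.numeric(onsets >= onset_s & onsets < onset_s + block_length_s)
  if (is.null(hrf_params)) {
    reg <- box
  } else {
    tg <- seq(0, scan_s, by = dt)
    boxg <- as.numeric(tg >= onset_s & tg < onset_s + block_length_s)
    h <- hrf(tg, hrf_params)
    full <- convolve(boxg, rev(h), type = "open")[seq_along(tg)] * dt
    # the FFT-based convolution leaves ~1e-16 ringing; the response is
    # causal, so the regressor is identically zero before the onset
    full[tg < onset_s] <- 0
    reg <- approx(tg, full, xout = onsets)$y
    reg[onsets < onset_s] <- 0
  }
  m <- max(reg)
  if (m > 0) reg <- reg / m
  reg
}

#' Build the activation-model design matrix
#'
#' One boxcar of `block_length_s` seconds starting at the injection onset,
#' convolved with the HRF on a fine grid, sampled at volume onsets and
#' peak-normalised to 1 ("task" column), plus intercept and centred linear
#' drift columns. The block length models the duration of the neural
#' response epoch; 25 s is the published default, selected by the
#' block-length sweep as the value maximising ION activation.
#'
#' @param n_volumes volumes per scan.
#' @param tr_s repetition time, s.
#' @param onset_s injection onset within the scan, s (default 234).
#' @param block_length_s modelled response duration, s (default 25).
#' @param hrf_params list from [hrf_params()], or NULL for a unit-impulse
#'   HRF (regressor = raw boxcar).
#' @param nuisance optional matrix (or vector) of extra nuisance columns —
#'   typically the per-volume heart-rate regressor — appended to the design
#'   after mean-centring, so the task beta is estimated jointly with the
#'   cardiovascular artifact (equivalent, by the Frisch-Waugh theorem, to
#'   fitting the task on nuisance-regressed data with the same columns, and
#'   unbiased where sequential projection would attenuate the task effect).
#' @return object of class `task_design`: list with `X` (matrix with columns
#'   task, intercept, drift, nuisance...), `block_length_s`, `onset_s`,
#'   `tr_s`.
#' @export
build_design <- function(n_volumes, tr_s, onset_s = 234, block_length_s = 25,
                         hrf_params = phtremor::hrf_params(),
                         nuisance = NULL) {
  reg <- task_regressor(n_volumes, tr_s, onset_s, block_length_s, hrf_params)
  dr <- seq_len(n_volumes) - (n_volumes + 1) / 2
  X <- cbind(task = reg, intercept = rep(1, n_volumes), drift = dr / sd(dr))
  if (!is.null(nuisance)) {
    N <- as.matrix(nuisance)
    if (nrow(N) != n_volumes) stop("nuisance rows must equal n_volumes")
    N <- sweep(N, 2, colMeans(N))
    if (is.null(colnames(N)))
      colnames(N) <- paste0("nuisance", seq_len(ncol(N)))
    X <- cbind(X, N)
  }
  structure(list(X = X, block_length_s = block_length_s, onset_s = onset_s,
                 tr_s = tr_s, hrf_params = hrf_params),
            class = "task_design")
}

#' Voxelwise GLM fit of BOLD on the task design
#'
#' Per voxel, ordinary least squares of the series on the design; the
#' statistic maps refer to the task column. t = beta / SE with
#' df = n - rank(design); voxels with (numerically) zero residual variance
#' are flagged degenerate and their t is reported as 0 rather than infinite.
#'
#' @param bold a [bold4d].
#' @param design a `task_design` from [build_design()] or a design matrix
#'   whose first column (or column named "task") is the effect of interest.
#' @return list with `beta` and `t` [stat_map] objects (the t map carries a
#'   `degenerate` flag array).
#' @export
fit_glm <- function(bold, design) {
  X <- if (inherits(design, "task_design")) design$X else as.matrix(design)
  n <- n_volumes(bold)
  if (nrow(X) != n) stop("design rows must equal the number of volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  task_col <- which(colnames(X) == "task")
  if (length(task_col) == 0) task_col <- 1L
  d <- dim(bold$data)
  Y <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = n)) # volumes x voxels
  beta_all <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta_all
  df <- n - qrX$rank
  rss <- colSums(resid^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[task_col, task_col])
  beta <- beta_all[task_col, ]
  scale_ref <- colSums(Y^2) / n
  degenerate <- sigma2 <= 1e-20 * (scale_ref + 1)
  tval <- ifelse(degenerate, 0, beta / ifelse(se == 0, Inf, se))
  list(beta = stat_map(array(beta, dim = d[1:3]), kind = "beta", df = df),
       t = stat_map(array(tval, dim = d[1:3]), kind = "t", df = df,
                    degenerate = array(degenerate, dim = d[1:3])))
}

#' Percent signal change of a BOLD series
#'
#' Per voxel, 100 * (value - baseline mean) / baseline mean, with the
#' baseline mean taken over a pre-injection volume window.
#'
#' @param bold a [bold4d].
#' @param baseline_vols integer volume indices (1-based) forming the
#'   pre-injection baseline window.
#' @return a [bold4d] of percent-signal-change values.
#' @export
percent_signal_change <- function(bold, baseline_vols) {
  n <- n_volumes(bold)
  if (length(baseline_vols) == 0) stop("baseline window must be non-empty")
  if (any(baseline_vols < 1) || any(baseline_vols > n))
    stop("baseline window outside the scan")
  d <- dim(bold$data)
  Y <- matrix(bold$data, nrow = prod(d[1:3]), ncol = n)
  mu <- rowMeans(Y[, baseline_vols, drop = FALSE])
  if (any(mu == 0)) stop("baseline mean is zero in at least one voxel")
  psc <- 100 * (Y / mu - 1)
  bold4d(array(psc, dim = d), tr_s = bold$tr_s,
         voxel_size_mm = bold$voxel_size_mm)
}

# shift an array by `off` voxels along `axis` (spatial axes only), zero
# padding; works for 3D volumes and 4D series alike
shift3 <- function(arr, off, axis) {
  if (off == 0) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (abs(off) >= n) return(out)
  if (off > 0) {
    dst[[axis]] <- (off + 1):n
    src[[axis]] <- 1:(n - off)
  } else {
    dst[[axis]] <- 1:(n + off)
    src[[axis]] <- (1 - off):n
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(arr), src)))))
}

#' Spatially smooth a 3D volume with a Gaussian kernel
#'
#' Separable convolution with sigma = FWHM / sqrt(8 ln 2) per axis,
#' expressed in voxel units via the voxel size; the discrete kernel is the
#' Gaussian evaluated at voxel-centre offsets and normalised to unit sum.
#' Boundary handling is zero padding, so values within a kernel radius of
#' the edge are attenuated; interior values are preserved in the mean.
#' `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array, or a 4D array / [bold4d] smoothed
#'   volume-by-volume along its spatial axes.
#' @param fwhm_mm full width at half maximum of the kernel, mm (the
#'   published preprocessing uses 2.8 mm).
#' @param voxel_size_mm length-3 voxel size, mm (taken from the object for
#'   a [bold4d]).
#' @return smoothed array of the input shape (a [bold4d] comes back as one).
#' @export
smooth_gaussian <- function(volume, fwhm_mm = 2.8,
                            voxel_size_mm = c(1.7, 1.7, 2.4)) {
  if (inherits(volume, "bold4d")) {
    sm <- smooth_gaussian(volume$data, fwhm_mm, volume$voxel_size_mm)
    return(bold4d(sm, tr_s = volume$tr_s,
                  voxel_size_mm = volume$voxel_size_mm))
  }
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(volume)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  out <- volume
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / voxel_size_mm[axis]
    r <- max(1L, ceiling(4 * sigma_vox))
    off <- (-r):r
    k <- exp(-(off^2) / (2 * sigma_vox^2))
    k <- k / sum(k)
    acc <- array(0, dim(out))
    for (j in seq_along(off)) acc <- acc + k[j] * shift3(out, off[j], axis)
    out <- acc
  }
  out
}

one_sample_t_core <- function(M, d3, df) {
  n <- nrow(M)
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  degenerate <- s == 0
  tval <- ifelse(degenerate, 0, mu / (s / sqrt(n)))
  pval <- ifelse(degenerate, 1, 2 * pt(-abs(tval), df = df))
  list(t = stat_map(array(tval, dim = d3), kind = "t", df = df,
                    degenerate = array(degenerate, dim = d3)),
       p = stat_map(array(pval, dim = d3), kind = "p", df = df))
}

#' Group-level one-sample t map
#'
#' Per voxel t = mean / (sd / sqrt(n)) with df = n - 1 across subjects'
#' beta maps, with two-sided p. Voxels whose across-subject sd is zero are
#' flagged degenerate (t = 0, p = 1) rather than reported infinite.
#'
#' @param beta_maps list of congruent [stat_map]s (or 3D arrays), one per
#'   subject/session.
#' @return list with `t` and `p` [stat_map]s.
#' @export
group_one_sample_t <- function(beta_maps) {
  if (length(beta_maps) < 2) stop("need at least 2 maps")
  arrs <- lapply(beta_maps, function(m) if (inherits(m, "stat_map")) m$values else m)
  d3 <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d3), TRUE)))
    stop("maps must share one grid")
  M <- do.call(rbind, lapply(arrs, as.vector)) # subjects x voxels
  one_sample_t_core(M, d3, df = length(arrs) - 1L)
}

#' Paired t map between two conditions
#'
#' One-sample t on per-subject difference maps (a - b); used to contrast
#' each harmaline session against the saline control at an uncorrected
#' threshold (p < 0.005 in the published analysis).
#'
#' @param maps_a,maps_b lists of per-subject [stat_map]s (or 3D arrays) in
#'   matched order.
#' @return list with `t` and `p` [stat_map]s (df = n - 1).
#' @export
paired_t <- function(maps_a, maps_b) {
  if (length(maps_a) != length(maps_b))
    stop("paired conditions must have equal subject counts")
  diffs <- Map(function(a, b) {
    va <- if (inherits(a, "stat_map")) a$values else a
    vb <- if (inherits(b, "stat_map")) b$values else b
    va - vb
  }, maps_a, maps_b)
  group_one_sample_t(diffs)
}

#' Benjamini-Hochberg FDR threshold of a p map
#'
#' Step-up BH over all in-mask voxels at rate `q`; returns the rejection
#' mask and the largest rejected p (the data-dependent critical p).
#'
#' @param p_map a [stat_map] of p-values or a numeric array/vector in
#'   \[0, 1\].
#' @param q false discovery rate (published group maps use q = 0.0005).
#' @param mask optional logical array restricting the family of tests.
#' @return list with `mask` (logical, same shape as input), `critical_p`
#'   (NA when nothing is rejected) and `n_rejected`.
#' @export
fdr_threshold <- function(p_map, q = 0.0005, mask = NULL) {
  vals <- if (inherits(p_map, "stat_map")) p_map$values else p_map
  sel <- if (is.null(mask)) rep(TRUE, length(vals)) else as.vector(mask)
  p <- as.vector(vals)[sel]
  if (length(p) == 0) stop("empty p-value set")
  if (min(p) < 0 || max(p) > 1) stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  below <- p[o] <= q * seq_len(m) / m
  k <- if (any(below)) max(which(below)) else 0L
  crit <- if (k > 0) p[o][k] else NA_real_
  rej_local <- logical(m)
  if (k > 0) rej_local[p <= crit] <- TRUE
  rej <- logical(length(vals))
  rej[sel] <- rej_local
  out_mask <- if (is.array(vals)) array(rej, dim(vals)) else rej
  list(mask = out_mask, critical_p = crit, n_rejected = sum(rej))
}

#' Sweep the modelled block length against a target region
#'
#' Fits the GLM once per candidate block length and scores each fit over a
#' target voxel mask (the ION in the published analysis, as the presumed
#' tremor pacemaker); the selected length is the score argmax, with ties
#' broken toward the shortest candidate (the most conservative model).
#'
#' @param bold a [bold4d] (artifact-corrected).
#' @param candidate_lengths_s numeric vector of block lengths to try, s.
#' @param target_mask logical 3D array of target voxels (non-empty).
#' @param onset_s injection onset, s.
#' @param hrf_params HRF parameters for [build_design()].
#' @param score `"mean_t"` (default, mean t over the mask), `"peak_t"`, or
#'   `"n_voxels"` (suprathreshold count at `score_t_threshold`).
#' @param score_t_threshold t threshold used only by `score = "n_voxels"`.
#' @param nuisance optional nuisance columns passed to [build_design()].
#' @return list with `best_length_s` and `table` (data.frame of
#'   block_length_s, score).
#' @export
block_length_sweep <- function(bold, candidate_lengths_s, target_mask,
                               onset_s = 234,
                               hrf_params = phtremor::hrf_params(),
                               score = c("mean_t", "peak_t", "n_voxels"),
                               score_t_threshold = 3, nuisance = NULL) {
  score <- match.arg(score)
  if (length(candidate_lengths_s) == 0) stop("no candidate block lengths")
  if (!any(target_mask)) stop("target mask is empty")
  lens <- sort(unique(candidate_lengths_s))
  scores <- vapply(lens, function(L) {
    des <- build_design(n_volumes(bold), bold$tr_s, onset_s,
                        block_length_s = L, hrf_params = hrf_params,
                        nuisance = nuisance)
    tmap <- fit_glm(bold, des)$t$values
    switch(score,
           mean_t = mean(tmap[target_mask]),
           peak_t = max(tmap[target_mask]),
           n_voxels = sum(tmap[target_mask] >= score_t_threshold))
  }, numeric(1))
  best <- lens[which.max(scores)] # first max = shortest on ties
  list(best_length_s = best,
       table = data.frame(block_length_s = lens, score = scores))
}

# 26-connectivity connected components of a logical 3D mask;
# returns an integer label array (0 outside the mask)
label_components_26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(labels)
  lab <- 0L
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    lab <- lab + 1L
    queue <- matrix(v, ncol = 3)
    labels[v[1], v[2], v[3]] <- lab
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      cand <- sweep(nb, 2, cur, "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        w <- cand[j, ]
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- lab
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

#' Cluster peaks of a thresholded statistic map
#'
#' Labels 26-connectivity components of suprathreshold voxels and reports,
#' per cluster, the peak coordinates in mm (offsets from the volume centre,
#' one decimal), cluster size, peak t, the atlas ROI name at the peak and
#' the hemisphere from the sign of x (x > 0 is left, x < 0 right, 0 both) —
#' the layout of a standard activation peak table.
#'
#' @param t_map a t-statistic [stat_map].
#' @param threshold voxels with t >= threshold enter clusters.
#' @param min_cluster minimum cluster extent in voxels (smaller components
#'   are dropped; default 20).
#' @param atlas optional [atlas_volume] naming the area at each peak.
#' @param voxel_size_mm voxel size, mm (taken from `atlas` when given).
#' @return data.frame with columns hemisphere, area, x, y, z, cluster_size,
#'   t — empty (0 rows) when nothing is suprathreshold.
#' @export
cluster_peaks <- function(t_map, threshold, min_cluster = 20, atlas = NULL,
                          voxel_size_mm = c(1.7, 1.7, 2.4)) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  vals <- t_map$values
  if (!is.null(atlas)) voxel_size_mm <- atlas$voxel_size_mm
  mask <- vals >= threshold
  empty <- data.frame(hemisphere = character(), area = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      cluster_size = integer(), t = numeric())
  if (!any(mask)) return(empty)
  labels <- label_components_26(mask)
  rows <- list()
  center <- (dim(vals) + 1) / 2
  for (lab in seq_len(max(labels))) {
    vox <- which(labels == lab, arr.ind = TRUE)
    if (nrow(vox) < min_cluster) next
    tv <- vals[vox]
    peak <- vox[which.max(tv), ]
    mm <- round((peak - center) * voxel_size_mm, 1)
    area <- if (is.null(atlas)) NA_character_ else {
      l <- atlas$labels[peak[1], peak[2], peak[3]]
      if (l == 0L) "unlabeled" else
        names(atlas$label_table)[match(l, atlas$label_table)]
    }
    hemi <- if (mm[1] > 0) "L" else if (mm[1] < 0) "R" else "L/R"
    rows[[length(rows) + 1]] <-
      data.frame(hemisphere = hemi, area = area, x = mm[1], y = mm[2],
                 z = mm[3], cluster_size = nrow(vox), t = max(tv))
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$cluster_size), , drop = FALSE]
}
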