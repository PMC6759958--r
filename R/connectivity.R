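#' ROI-mean time series from a BOLD volume
#'
#' Per volume, the unweighted mean over each named ROI's voxels — the input
#' to the inter-ROI partial-correlation analysis.
#'
#' @param bold a [bold4d].
#' @param atlas an [atlas_volume] on the same grid.
#' @param roi_names ROIs to extract (default: every named ROI, in atlas
#'   order); each must be non-empty in the atlas.
#' @return a [roi_series] (ROIs x volumes).
#' @export
roi_mean_series <- function(bold, atlas, roi_names = names(atlas$label_table)) {
  check_congruent(bold, atlas)
  n <- n_volumes(bold)
  Y <- matrix(bold$data, nrow = prod(dim(bold$data)[1:3]), ncol = n)
  lab_vec <- as.vector(atlas$labels)
  out <- matrix(NA_real_, nrow = length(roi_names), ncol = n,
                dimnames = list(roi_names, NULL))
  for (roi in roi_names) {
    sel <- lab_vec == atlas$label_table[[roi]]
    if (!any(sel)) stop(sprintf("ROI '%s' is empty in the atlas", roi))
    out[roi, ] <- colMeans(Y[sel, , drop = FALSE])
  }
  roi_series(out, tr_s = bold$tr_s)
}

# partial correlation matrix from the inverse sample covariance
# (rows of `mat` = variables); optional ridge for singular covariance
pcor_from_matrix <- function(mat, ridge = TRUE) {
  X <- mat - rowMeans(mat)
  S <- tcrossprod(X) / (ncol(X) - 1)
  P <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(P)) {
    if (!ridge) stop("singular ROI covariance matrix")
    eps <- 1e-8 * sum(diag(S)) / nrow(S)
    warning("singular ROI covariance; applying ridge epsilon = 1e-8 * trace/n")
    P <- solve(S + diag(eps, nrow(S)))
  }
  d <- 1 / sqrt(diag(P))
  R <- -P * tcrossprod(d)
  diag(R) <- 1
  R
}

#' Partial-correlation matrix of ROI time series
#'
#' The correlation between each ROI pair conditioned on all remaining ROIs,
#' computed from the inverse sample covariance:
#' rho_ij = -P_ij / sqrt(P_ii P_jj). Rows are demeaned over the supplied
#' epoch only, so a split epoch never leaks the other epoch's mean.
#' Conditioning on the remaining regions strips signal components shared
#' across the network (global drug and vascular effects), leaving a
#' quantity closer to direct interaction than the plain correlation.
#'
#' Optionally, per-cell permutation p-values are attached by shuffling one
#' ROI's sample order (see [permutation_test()]).
#'
#' @param series a [roi_series] (or numeric matrix with rownames); needs
#'   more volumes than ROIs + 1 and no constant row.
#' @param n_perm number of permutations for p-values (0 = none).
#' @param seed RNG seed for the permutations.
#' @return object of class `pcor_matrix`: list with `values` (symmetric,
#'   unit diagonal), and when `n_perm > 0` also `p_values`, `n_perm`,
#'   `seed`.
#' @export
partial_correlation <- function(series, n_perm = 0, seed = 1L) {
  M <- if (inherits(series, "roi_series")) series$values else as.matrix(series)
  k <- nrow(M)
  if (ncol(M) <= k + 1)
    stop("need more volumes than ROIs + 1 for a partial correlation")
  if (any(apply(M, 1, sd) == 0)) stop("constant ROI series")
  R <- pcor_from_matrix(M)
  dimnames(R) <- list(rownames(M), rownames(M))
  out <- structure(list(values = R, p_values = NULL, n_perm = n_perm,
                        seed = as.integer(seed)),
                   class = "pcor_matrix")
  if (n_perm > 0) {
    P <- matrix(NA_real_, k, k, dimnames = dimnames(R))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      P[i, j] <- P[j, i] <- permutation_test(
        M, roi_a = i, roi_b = j, n_perm = n_perm,
        seed = derive_seed(seed, i, j))$p
    }
    out$p_values <- P
  }
  out
}

#' @export
print.pcor_matrix <- function(x, ...) {
  cat(sprintf("<pcor_matrix> %d ROIs%s\n", nrow(x$values),
              if (!is.null(x$p_values))
                sprintf(", permutation p-values (n = %d)", x$n_perm) else ""))
  print(round(x$values, 3))
  invisible(x)
}

#' Split ROI series into pre- and post-injection epochs
#'
#' Volumes are assigned by onset time: the pre epoch takes onsets inside
#' the closed interval `pre_s`, the post epoch onsets in the half-open
#' interval \[post_s\[1\], post_s\[2\]). With the default epochs and TR 2 s
#' that is 117 pre volumes (onsets 0-232 s) and 125 post volumes (onsets
#' 234-482 s); the two epochs never overlap.
#'
#' @param series a [roi_series].
#' @param pre_s,post_s numeric length-2 epoch bounds in seconds (defaults
#'   c(0, 232) and c(234, 484)).
#' @return list with `pre` and `post` [roi_series].
#' @export
split_epochs <- function(series, pre_s = c(0, 232), post_s = c(234, 484)) {
  onsets <- (seq_len(ncol(series$values)) - 1) * series$tr_s
  scan_end <- ncol(series$values) * series$tr_s
  if (pre_s[1] < 0 || post_s[2] > scan_end + 1e-9)
    stop("epochs must lie within the scan")
  if (pre_s[2] >= post_s[1]) stop("epochs must be disjoint (pre before post)")
  pre_idx <- which(onsets >= pre_s[1] & onsets <= pre_s[2])
  post_idx <- which(onsets >= post_s[1] & onsets < post_s[2])
  if (length(pre_idx) == 0 || length(post_idx) == 0)
    stop("an epoch contains no volumes")
  list(pre = roi_series(series$values[, pre_idx, drop = FALSE], series$tr_s),
       post = roi_series(series$values[, post_idx, drop = FALSE],
                         series$tr_s))
}

#' Drug-induced connectivity change matrices
#'
#' The primary contrast isolating drug-specific connectivity change is the
#' post-injection harmaline matrix minus the post-injection saline matrix;
#' the post-minus-pre difference within each condition is also reported,
#' since both operations are part of the published analysis and their exact
#' composition in the figures is not stated.
#'
#' @param harm_pre,harm_post,sal_pre,sal_post `pcor_matrix` objects on the
#'   same ROI set.
#' @return list with `delta` (harm_post - sal_post, the primary output),
#'   `harm_post_minus_pre`, `sal_post_minus_pre`.
#' @export
connectivity_change <- function(harm_pre, harm_post, sal_pre, sal_post) {
  mats <- list(harm_pre, harm_post, sal_pre, sal_post)
  rois <- rownames(harm_pre$values)
  if (!all(vapply(mats, function(m) identical(rownames(m$values), rois),
                  TRUE)))
    stop("ROI sets of the four matrices do not match")
  list(delta = harm_post$values - sal_post$values,
       harm_post_minus_pre = harm_post$values - harm_pre$values,
       sal_post_minus_pre = sal_post$values - sal_pre$values)
}

#' Permutation test of one partial-correlation cell
#'
#' Null distribution by randomly shuffling the sample order of one ROI while
#' all others keep their order, recomputing the partial correlation each
#' time (n = 2000 in the published analysis). Shuffling whole time samples
#' destroys the cross- and auto-correlation of that ROI. The two-sided
#' p-value uses the add-one convention,
#' p = (1 + #\{|null| >= |observed|\}) / (n_perm + 1), so p is never 0 and
#' its minimum is 1 / (n_perm + 1). Deterministic given the seed.
#'
#' @param series a [roi_series] or numeric matrix (rows = ROIs).
#' @param roi_a ROI whose sample order is shuffled (name or index).
#' @param roi_b the partner ROI (name or index).
#' @param n_perm number of permutations (>= 1; default 2000).
#' @param seed RNG seed.
#' @return list with `observed`, `p`, `null` (the permuted values).
#' @export
permutation_test <- function(series, roi_a, roi_b, n_perm = 2000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  M <- if (inherits(series, "roi_series")) series$values else as.matrix(series)
  ia <- if (is.character(roi_a)) match(roi_a, rownames(M)) else roi_a
  ib <- if (is.character(roi_b)) match(roi_b, rownames(M)) else roi_b
  if (is.na(ia) || is.na(ib)) stop("unknown ROI")
  obs <- pcor_from_matrix(M)[ia, ib]
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      Mp <- M
      Mp[ia, ] <- Mp[ia, sample.int(ncol(M))]
      pcor_from_matrix(Mp)[ia, ib]
    }, numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p = p, null = null)
}
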