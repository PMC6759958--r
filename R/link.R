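#' Voxelwise regression of activation betas on tremor severity
#'
#' Links imaging to behaviour: per voxel, a simple linear regression of the
#' GLM beta coefficient on the paired session's maximum tremor index,
#' beta = a + b * tremor, with observations pooled across animals and
#' sessions (fMRI session k is paired with behavioural session k). Reports
#' the slope, its t statistic (df = n - 2) and the two-sided p; regions
#' genuinely driven by the tremor generator show up as positive slopes at
#' the uncorrected p < 0.05 used in the published analysis.
#'
#' @param beta_maps list of congruent beta [stat_map]s (or 3D arrays), one
#'   per (animal, session) observation; at least 3.
#' @param tremor numeric vector of the paired maximum tremor indices, same
#'   length and order as `beta_maps`; must have nonzero variance.
#' @return list with `slope`, `t` and `p` [stat_map]s; voxels with zero
#'   residual variance (exact linear fit) are flagged degenerate on the t
#'   map (t = 0, p = 1).
#' @export
regress_beta_on_tremor <- function(beta_maps, tremor) {
  n <- length(beta_maps)
  if (n < 3) stop("need at least 3 (beta map, tremor) observations")
  if (length(tremor) != n)
    stop("tremor vector must match the number of beta maps")
  if (sd(tremor) == 0) stop("constant tremor index: slope is undefined")
  arrs <- lapply(beta_maps, function(m)
    if (inherits(m, "stat_map")) m$values else m)
  d3 <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d3), TRUE)))
    stop("beta maps must share one grid")
  Y <- do.call(rbind, lapply(arrs, as.vector)) # observations x voxels
  x <- tremor - mean(tremor)
  sxx <- sum(x^2)
  b <- as.vector(crossprod(x, Y)) / sxx # centred x kills the intercept term
  a <- colMeans(Y)
  fit <- outer(x, b) + matrix(a, n, length(a), byrow = TRUE)
  rss <- colSums((Y - fit)^2)
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  scale_ref <- colSums(Y^2) / n
  degenerate <- sigma2 <= 1e-20 * (scale_ref + 1)
  tval <- ifelse(degenerate, 0, b / ifelse(se == 0, Inf, se))
  pval <- ifelse(degenerate, 1, 2 * pt(-abs(tval), df = df))
  list(slope = stat_map(array(b, dim = d3), kind = "slope", df = df),
       t = stat_map(array(tval, dim = d3), kind = "t", df = df,
                    degenerate = array(degenerate, dim = d3)),
       p = stat_map(array(pval, dim = d3), kind = "p", df = df))
}

#' Enrichment of suprathreshold voxels in target ROIs
#'
#' Odds ratio comparing the suprathreshold rate inside a set of target ROIs
#' with the rate elsewhere — the summary used to check that tremor-linked
#' voxels concentrate in the tremor-generating circuit (ION, cerebellum).
#' A 0.5 continuity correction is applied when any cell is empty.
#'
#' @param p_map a p-value [stat_map].
#' @param atlas an [atlas_volume].
#' @param target_rois character vector of ROI names forming the target set.
#' @param p_threshold suprathreshold cut (default 0.05).
#' @param positive_only optional slope/t [stat_map]: when given, only
#'   voxels with positive statistic count as suprathreshold.
#' @return list with `odds_ratio` and the 2x2 `counts` table.
#' @export
roi_enrichment <- function(p_map, atlas, target_rois,
                           p_threshold = 0.05, positive_only = NULL) {
  sig <- p_map$values < p_threshold
  if (!is.null(positive_only)) sig <- sig & positive_only$values > 0
  target <- array(FALSE, dim(atlas$labels))
  for (roi in target_rois) target <- target | roi_mask(atlas, roi)
  a <- sum(sig & target); b <- sum(!sig & target)
  c <- sum(sig & !target); d <- sum(!sig & !target)
  cc <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  or <- ((a + cc) / (b + cc)) / ((c + cc) / (d + cc))
  list(odds_ratio = or,
       counts = matrix(c(a, b, c, d), 2, 2,
                       dimnames = list(c("sig", "nonsig"),
                                       c("target", "other"))))
}
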