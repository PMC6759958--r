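test_that("HRF is causal with its peak at the configured delay", {
  expect_equal(hrf(0), 0)
  expect_equal(hrf(-5), 0)
  expect_equal(hrf(c(-2, 0)), c(0, 0))
  # dense grid-search oracle: argmax on a 1 ms grid ~ 5 s peak delay
  tg <- seq(0, 30, by = 0.001)
  h <- hrf(tg)
  expect_equal(tg[which.max(h)], 5, tolerance = 2e-3)
  # late undershoot is negative
  expect_lt(min(h), 0)
  expect_error(hrf(1, hrf_params(peak_delay_s = -1)), "positive")
})

test_that("task design is zero before the injection and peak-normalised", {
  des <- build_design(242, 2, onset_s = 234, block_length_s = 25)
  reg <- des$X[, "task"]
  # volumes with onsets 0..232 s (the first 117) precede the injection
  expect_true(all(reg[1:117] == 0))
  expect_true(any(reg[118:242] > 0))
  expect_equal(max(reg), 1)
  expect_error(build_design(242, 2, block_length_s = 0), "positive")
  expect_error(build_design(242, 2, onset_s = 480, block_length_s = 25),
               "within the scan")
  # unit-impulse HRF: the task column is the boxcar itself
  des0 <- build_design(100, 2, onset_s = 50, block_length_s = 20,
                       hrf_params = NULL)
  onsets <- (0:99) * 2
  expect_equal(des0$X[, "task"],
               as.numeric(onsets >= 50 & onsets < 70), ignore_attr = TRUE)
})

test_that("voxelwise GLM recovers exact effects and flags degeneracy", {
  des <- build_design(100, 2, onset_s = 60, block_length_s = 25)
  reg <- des$X[, "task"]
  y1 <- 2 * reg + 5            # exact linear model
  y2 <- rep(7, 100)            # constant series
  arr <- array(c(y1, y2), dim = c(2, 1, 1, 100))
  arr[1, 1, 1, ] <- y1; arr[2, 1, 1, ] <- y2
  g <- fit_glm(bold4d(arr, tr_s = 2), des)
  expect_equal(g$beta$values[1, 1, 1], 2, tolerance = 1e-8)
  expect_equal(g$beta$values[2, 1, 1], 0, tolerance = 1e-12)
  expect_true(g$t$degenerate[1, 1, 1]) # zero residual variance
  expect_true(g$t$degenerate[2, 1, 1])
  expect_equal(g$t$values[2, 1, 1], 0)
  expect_equal(g$t$df, 100 - 3)
})

test_that("GLM t equals the hand-computed normal-equations oracle", {
  set.seed(3)
  n <- 10
  X <- cbind(task = c(0, 0, 0, 1, 1, 1, 1, 0, 0, 0), intercept = rep(1, n))
  y <- rnorm(n, mean = 2)
  g <- fit_glm(bold4d(array(y, c(1, 1, 1, n)), tr_s = 1), X)
  b <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% b
  s2 <- sum(r^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
  expect_equal(g$beta$values[1, 1, 1], b[1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(g$t$values[1, 1, 1], b[1] / se, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("percent signal change is exact arithmetic on the baseline", {
  arr <- array(100, c(1, 1, 1, 6))
  arr[1, 1, 1, ] <- c(100, 100, 102, 104, 98, 100)
  psc <- percent_signal_change(bold4d(arr, tr_s = 2), baseline_vols = 1:2)
  expect_equal(as.vector(psc$data), c(0, 0, 2, 4, -2, 0))
  # constant series -> 0 everywhere
  cst <- percent_signal_change(bold4d(array(7, c(2, 2, 1, 5)), tr_s = 2), 1:2)
  expect_true(all(cst$data == 0))
  # epoch mean psc equals the mean of the per-volume psc values (8-s epoch
  # = 4 volumes at TR 2)
  expect_equal(mean(psc$data[1, 1, 1, 3:6]), mean(c(2, 4, -2, 0)))
  zer <- bold4d(array(0, c(1, 1, 1, 4)), tr_s = 2)
  expect_error(percent_signal_change(zer, 1:2), "zero")
})

test_that("Gaussian smoothing matches the direct kernel oracle", {
  # fwhm 0 is the identity
  v <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  expect_identical(smooth_gaussian(v, 0), v)
  # constant volume unchanged in the interior (zero padding attenuates edges)
  cst <- array(5, c(11, 11, 11))
  sm <- smooth_gaussian(cst, 2.8, c(1, 1, 1))
  expect_equal(sm[6, 6, 6], 5, tolerance = 1e-6)
  # unit impulse reproduces the separable Gaussian kernel with
  # sigma = 2.8 / 2.3548 mm, total mass ~ 1
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  sm <- smooth_gaussian(imp, 2.8, c(1, 1, 1))
  sigma <- 2.8 / sqrt(8 * log(2))
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expect_equal(sm[8 + (-r:r), 8, 8], k1 * k1[r + 1] * k1[r + 1],
               tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # interior-supported input conserves the volume mean
  v2 <- array(0, c(15, 15, 15))
  v2[6:10, 6:10, 6:10] <- rnorm(125)
  expect_equal(mean(smooth_gaussian(v2, 2.8, c(1, 1, 1))), mean(v2),
               tolerance = 1e-12)
  expect_error(smooth_gaussian(v, -1), "non-negative")
})

test_that("group and paired t maps match hand formulas and flag degeneracy", {
  mk <- function(x) array(x, c(1, 1, 1))
  g <- group_one_sample_t(list(mk(-1), mk(1)))
  expect_equal(g$t$values[1, 1, 1], 0)
  g2 <- group_one_sample_t(lapply(1:5, mk))
  expect_equal(g2$t$values[1, 1, 1], 3 / (sd(1:5) / sqrt(5)),
               tolerance = 1e-10)
  expect_equal(g2$t$values[1, 1, 1], 4.2426, tolerance = 1e-4)
  expect_equal(g2$t$df, 4L)
  # identical nonzero betas: degenerate, not infinite
  g3 <- group_one_sample_t(list(mk(2), mk(2), mk(2)))
  expect_true(g3$t$degenerate[1, 1, 1])
  expect_true(is.finite(g3$t$values[1, 1, 1]))
  expect_error(group_one_sample_t(list(mk(1))), "at least 2")

  # paired: differences (1,1,1,1,0) -> t = 0.8 / (0.4472/sqrt(5)) = 4
  a <- lapply(c(2, 3, 4, 5, 6), mk)
  b <- lapply(c(1, 2, 3, 4, 6), mk)
  p <- paired_t(a, b)
  expect_equal(p$t$values[1, 1, 1], 4, tolerance = 1e-4)
  pid <- paired_t(a, a)
  expect_true(pid$t$degenerate[1, 1, 1])
  expect_error(paired_t(a, b[1:3]), "equal subject counts")
})

test_that("BH-FDR matches the exhaustive oracle and is monotone in q", {
  p <- c(0.001, 0.02, 0.03, 0.9)
  out <- fdr_threshold(p, q = 0.05)
  expect_equal(out$n_rejected, 3L)
  expect_equal(out$critical_p, 0.03)
  expect_equal(out$mask, bh_oracle(p, 0.05))

  expect_equal(fdr_threshold(rep(1, 10), q = 0.05)$n_rejected, 0L)

  set.seed(5)
  for (i in 1:20) {
    pv <- runif(50)^2
    q1 <- 0.01; q2 <- 0.1
    r1 <- fdr_threshold(pv, q1)$mask
    r2 <- fdr_threshold(pv, q2)$mask
    expect_equal(r1, bh_oracle(pv, q1))
    expect_equal(r2, bh_oracle(pv, q2))
    expect_true(all(r2[r1])) # rejections at the stricter rate are nested
  }
  expect_error(fdr_threshold(numeric(0), 0.05), "empty")
})

test_that("block-length sweep degenerate cases behave", {
  cfg <- quick_config()
  atl <- make_atlas()
  sim <- simulate_bold_session(atl, cfg, quiet_truth(), "harmaline")
  ion <- atl$labels == atl$label_table[["ION"]]
  one <- block_length_sweep(sim$bold, 25, ion)
  expect_equal(one$best_length_s, 25)
  expect_error(block_length_sweep(sim$bold, c(10, 25),
                                  array(FALSE, dim(atl$labels))), "empty")
  expect_error(block_length_sweep(sim$bold, numeric(0), ion), "candidate")
})

test_that("cluster peaks match exhaustive component labelling", {
  tm <- array(0, c(10, 10, 10))
  expect_equal(nrow(cluster_peaks(stat_map(tm, "t", df = 4), threshold = 3,
                                  min_cluster = 1)), 0L)
  # one 3x3x3 suprathreshold block: one cluster of 27, peak at the max voxel
  tm[4:6, 4:6, 4:6] <- 5
  tm[5, 5, 5] <- 9
  pk <- cluster_peaks(stat_map(tm, "t", df = 4), threshold = 3,
                      min_cluster = 1, voxel_size_mm = c(1, 1, 1))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$cluster_size, 27L)
  expect_equal(pk$t, 9)
  expect_equal(c(pk$x, pk$y, pk$z), c(-0.5, -0.5, -0.5)) # voxel 5 vs centre 5.5
  expect_equal(names(pk),
               c("hemisphere", "area", "x", "y", "z", "cluster_size", "t"))

  # random masks: component count and sizes equal the exhaustive oracle
  set.seed(8)
  for (i in 1:3) {
    m <- array(runif(8 * 8 * 8) < 0.15, c(8, 8, 8))
    tmap <- array(as.numeric(m), c(8, 8, 8))
    pk <- cluster_peaks(stat_map(tmap, "t", df = 4), threshold = 0.5,
                        min_cluster = 1)
    lab <- label_components_oracle(m)
    expect_equal(nrow(pk), max(lab))
    expect_setequal(pk$cluster_size, as.integer(table(lab[lab > 0])))
  }

  # hemisphere from the x sign: positive x is left
  tm2 <- array(0, c(9, 9, 9)); tm2[8, 5, 5] <- 5
  pk2 <- cluster_peaks(stat_map(tm2, "t", df = 4), threshold = 3,
                       min_cluster = 1, voxel_size_mm = c(1, 1, 1))
  expect_equal(pk2$hemisphere, "L")
  expect_equal(pk2$x, 3)
})
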