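test_that("windowed amplitude spectrum matches the direct DFT oracle", {
  expect_error(window_spectrum(rnorm(999), 100), "exactly 1000")
  z <- window_spectrum(rep(0, 1000), 100)
  expect_true(all(z$amplitude == 0))
  expect_equal(z$freq_hz[2] - z$freq_hz[1], 0.1) # 1 / bin width

  # unit 13 Hz sinusoid: maximum at the 13.0 Hz bin, amplitude ~ 1 after
  # the Hann coherent-gain scaling, equal to the brute-force DFT oracle
  t <- (0:999) / 100
  x <- sin(2 * pi * 13 * t + 0.4)
  sp <- window_spectrum(x, 100)
  expect_equal(sp$freq_hz[which.max(sp$amplitude)], 13)
  expect_equal(sp$amplitude[sp$freq_hz == 13], 1, tolerance = 1e-3)
  oracle <- dft_spectrum_oracle(x, 100)
  expect_equal(sp$amplitude, oracle$amplitude, tolerance = 1e-10)

  # random segment: full spectrum equals the oracle
  set.seed(2)
  y <- rnorm(500)
  expect_equal(window_spectrum(y, 50, bin_width_s = 10)$amplitude,
               dft_spectrum_oracle(y, 50)$amplitude, tolerance = 1e-10)
})

test_that("band means use half-open bands with the DC bin excluded", {
  spec <- data.frame(freq_hz = seq(0, 50, by = 0.1),
                     amplitude = rep(1, 501))
  expect_equal(band_mean(spec, 0, 10), 1)
  expect_equal(band_mean(spec, 10, 16), 1)
  # one nonzero bin inside the band -> amplitude / bin count
  spec2 <- spec; spec2$amplitude <- 0
  spec2$amplitude[spec2$freq_hz == 13] <- 6
  expect_equal(band_mean(spec2, 10, 16), 6 / 60) # bins 10.0 .. 15.9
  expect_equal(band_mean(spec2, 0, 10), 0)       # bins 0.1 .. 9.9, DC out
  # the 10 Hz bin belongs to the tremor band only
  spec3 <- spec; spec3$amplitude <- 0
  spec3$amplitude[spec3$freq_hz == 10] <- 1
  expect_equal(band_mean(spec3, 0, 10), 0)
  expect_gt(band_mean(spec3, 10, 16), 0)
  expect_error(band_mean(spec, 16, 10), "f_lo < f_hi")
  expect_error(band_mean(spec, 10, 80), "Nyquist")
})

test_that("per-bin tremor index equals the DFT oracle and is scale invariant", {
  set.seed(4)
  t <- (0:(100 * 40 - 1)) / 100
  x <- rnorm(length(t), sd = 0.5) + 0.8 * sin(2 * pi * 13 * t)
  tra <- accel_trace(x, rate_hz = 100)
  ser <- tremor_index_series(tra)
  expect_equal(length(ser$index), 4L)
  expect_equal(ser$index, tremor_index_oracle(x, 100), tolerance = 1e-10)
  # homogeneity: scaling the trace leaves the ratio untouched
  ser10 <- tremor_index_series(accel_trace(10 * x, rate_hz = 100))
  expect_equal(ser10$index, ser$index, tolerance = 1e-12)
})

test_that("tremor index grows strictly with tremor-band amplitude", {
  set.seed(6)
  t <- (0:999) / 100
  floor_noise <- rnorm(1000, sd = 0.5)
  idx <- vapply(c(0, 0.3, 0.6, 1.2, 2.4), function(a) {
    tremor_index_series(
      accel_trace(floor_noise + a * sin(2 * pi * 13 * t),
                  rate_hz = 100))$index
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("aggregation and baseline normalisation behave as documented", {
  set.seed(9)
  # stationary signal: all normalized values ~ 1
  x <- rnorm(100 * 1200, sd = 1)
  tra <- accel_trace(x, 100, events = list(baseline_start_s = 0,
                                           injection_s = 600, end_s = 1200))
  ser <- tremor_index_series(tra)
  nrm <- aggregate_and_normalize(ser, c(0, 600), window_s = 300)
  expect_true(all(abs(nrm$index - 1) < 0.2))
  expect_true(nrm$normalized)

  # step increase at injection: first post window > 1 and equal to the
  # oracle averaging of the per-bin indices
  t <- (0:(100 * 1200 - 1)) / 100
  y <- rnorm(length(t), sd = 0.5) +
    ifelse(t >= 600, 1.5, 0) * sin(2 * pi * 13 * t)
  trb <- accel_trace(y, 100, events = list(baseline_start_s = 0,
                                           injection_s = 600, end_s = 1200))
  serb <- tremor_index_series(trb)
  nrb <- aggregate_and_normalize(serb, c(0, 600), window_s = 300)
  expect_gt(nrb$index[3], 1)
  oracle_idx <- tremor_index_oracle(y, 100)
  base_mean <- mean(oracle_idx[1:60])
  expect_equal(nrb$index[3], mean(oracle_idx[61:90]) / base_mean,
               tolerance = 1e-10)

  expect_error(aggregate_and_normalize(serb, c(500, 700)), "pre-injection")
})

test_that("maximum index and duration summarise the normalised series", {
  mk <- function(vals, inj = 600) {
    structure(list(bin_start_s = seq(0, by = 300,
                                     length.out = length(vals)),
                   index = vals, bin_width_s = 300, normalized = TRUE,
                   baseline_mean = 1, baseline_window = c(0, 600),
                   events = list(baseline_start_s = 0, injection_s = inj,
                                 end_s = 300 * length(vals))),
              class = "tremor_index_series")
  }
  expect_equal(max_tremor_index(mk(c(1, 1, 5, 4, 3, 2))), 5)
  expect_equal(max_tremor_index(mk(rep(1, 6))), 1)
  # never suprathreshold -> 0 s
  expect_equal(tremor_duration(mk(c(1, 1, 1, 1, 1, 1))), 0)
  # exactly one contiguous 3-window run above threshold -> 900 s
  expect_equal(tremor_duration(mk(c(1, 1, 9, 9, 9, 1))), 900)
})

test_that("duration decreases across sessions as the tremor envelope decays", {
  cfg <- quick_config(seed = 3)
  tr <- session_truth(tremor_amplitude_g = 3, decay_factor = 0.5)
  sched <- list(list(kind = "behavior", interval_h = 0),
                list(kind = "behavior", interval_h = 72),
                list(kind = "behavior", interval_h = 72))
  cfgb <- quick_config(session_schedule = sched, seed = 3)
  durs <- vapply(1:3, function(s) {
    acc <- simulate_accelerometer(cfgb, tr, session_index = s,
                                  seed = derive_seed(3, s))
    nrm <- aggregate_and_normalize(tremor_index_series(acc), c(0, 600),
                                   window_s = 120)
    tremor_duration(nrm)
  }, numeric(1))
  expect_true(all(diff(durs) <= 0))
})

test_that("session trend statistics match hand-computed decompositions", {
  # identical sessions: paired t degenerate, ANOVA F ~ 0
  M <- matrix(rep(c(1, 2, 3), 2), ncol = 2)
  out <- session_trend_stats(M, M)
  expect_true(all(out$pairwise$degenerate))
  expect_equal(out$anova$F, 0)

  # two-session toy with constant differences: degenerate flag
  M2 <- matrix(c(1, 2, 3, 2, 3, 4), ncol = 2)
  out2 <- session_trend_stats(M2)
  expect_true(out2$pairwise$degenerate[1])

  # 3-group ANOVA equals the between/within mean-square ratio
  D <- cbind(c(1, 2, 3, 2), c(4, 6, 5, 7), c(2, 2, 3, 3))
  out3 <- session_trend_stats(D, D)
  grand <- mean(D)
  ssb <- 4 * sum((colMeans(D) - grand)^2)
  ssw <- sum(sweep(D, 2, colMeans(D))^2)
  expect_equal(out3$anova$F, (ssb / 2) / (ssw / 9), tolerance = 1e-12)
  expect_equal(out3$anova$df1, 2)
  expect_equal(out3$anova$df2, 9)
  # paired t on sessions 1 vs 2 equals the hand formula
  dif <- D[, 1] - D[, 2]
  texp <- mean(dif) / (sd(dif) / 2)
  row12 <- out3$pairwise[out3$pairwise$session_a == 1 &
                           out3$pairwise$session_b == 2, ]
  expect_equal(row12$t, texp, tolerance = 1e-12)

  expect_error(session_trend_stats(matrix(1:3, ncol = 1)), "2 sessions")
})
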