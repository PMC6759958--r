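test_that("make_atlas builds labelled disjoint blocks and rejects overlap", {
  blk <- function(x, y, z) matrix(c(x, y, z), nrow = 3, byrow = TRUE)
  atl <- make_atlas(c(8, 8, 8),
                    list(a = blk(c(1, 2), c(1, 2), c(1, 2)),
                         b = blk(c(5, 6), c(5, 6), c(5, 6))))
  expect_setequal(unique(as.vector(atl$labels)), c(0L, 1L, 2L))
  expect_equal(sum(atl$labels == 1L), 8L)
  expect_equal(sum(atl$labels == 2L), 8L)

  expect_error(make_atlas(c(8, 8, 8),
                          list(a = blk(c(1, 3), c(1, 3), c(1, 3)),
                               b = blk(c(2, 4), c(2, 4), c(2, 4)))),
               "overlap")
  expect_error(make_atlas(c(8, 8, 8), list()), "at least one ROI")
  expect_error(make_atlas(c(4, 4, 4),
                          list(a = blk(c(1, 5), c(1, 2), c(1, 2)))),
               "outside")
})

test_that("default atlas defines the six network ROIs plus the ION", {
  atl <- make_atlas()
  expect_setequal(names(atl$label_table),
                  c("SMC", "thalamus", "limbic", "cerebellum", "DCN",
                    "visual", "ION"))
  # every ROI non-empty
  for (roi in names(atl$label_table))
    expect_gt(sum(atl$labels == atl$label_table[[roi]]), 0)
})

test_that("heart-rate trace follows the bradycardia trajectory", {
  cfg <- quick_config()
  # zero drop -> constant at the 120 bpm anaesthetised baseline
  tr0 <- session_truth(hr_drop_bpm = 0, hr_noise_bpm = 0)
  hr0 <- simulate_heart_rate(cfg, tr0)
  expect_equal(unique(hr0$value), 120)

  # minimum is exactly baseline - drop at the configured time-to-nadir
  tr <- session_truth(hr_drop_bpm = 40, hr_noise_bpm = 0,
                      hr_time_to_nadir_s = 100)
  hr <- simulate_heart_rate(cfg, tr, sample_rate_hz = 20)
  expect_equal(min(hr$value), 80)
  expect_equal(hr$time_s[which.min(hr$value)],
               cfg$injection_onset_s + 100)
  # constant baseline before injection, recovery after nadir
  expect_true(all(hr$value[hr$time_s < cfg$injection_onset_s] == 120))
  after <- hr$value[hr$time_s > cfg$injection_onset_s + 100]
  expect_true(all(diff(after) >= 0))

  # closed-form oracle on a dense grid
  tgrid <- hr$time_s
  tp <- pmax(0, tgrid - cfg$injection_onset_s)
  g <- (1 - exp(-pmin(tp, 100) / tr$hr_tau_rise_s)) *
    exp(-pmax(0, tp - 100) / tr$hr_tau_recovery_s)
  expected <- 120 - 40 * g / (1 - exp(-100 / tr$hr_tau_rise_s))
  expect_equal(hr$value, expected, tolerance = 1e-12)

  expect_error(session_truth(hr_drop_bpm = 130), "baseline")
})

test_that("noiseless BOLD session is the exact sum of its components", {
  cfg <- quick_config()
  atl <- make_atlas()
  tr <- quiet_truth()
  sim <- simulate_bold_session(atl, cfg, tr, "harmaline")
  expect_equal(dim(sim$bold$data)[4], 242L)
  expect_equal(dim(sim$bold$data)[4] * sim$bold$tr_s, 484)

  # every ROI-mean series equals baseline * (1 + amplitude/100 * regressor)
  for (roi in c("ION", "cerebellum", "SMC")) {
    m <- atl$labels == atl$label_table[[roi]]
    series <- apply(sim$bold$data, 4, function(v) mean(v[m]))
    a <- tr$roi_amplitude_psc[[roi]]
    expect_equal(series, 1000 * (1 + a / 100 * sim$regressor),
                 tolerance = 1e-12)
  }
  # background voxels are flat at baseline
  expect_equal(unique(as.vector(sim$bold$data[1, 1, 1, ])), 1000)
})

test_that("BOLD sessions are deterministic per seed and saline is null", {
  cfg <- quick_config()
  atl <- make_atlas()
  tr <- session_truth()
  s1 <- simulate_bold_session(atl, cfg, tr, "harmaline", seed = 42)
  s2 <- simulate_bold_session(atl, cfg, tr, "harmaline", seed = 42)
  expect_identical(s1$bold$data, s2$bold$data)
  s3 <- simulate_bold_session(atl, cfg, tr, "harmaline", seed = 43)
  expect_false(identical(s1$bold$data, s3$bold$data))

  sal <- simulate_bold_session(atl, cfg, quiet_truth(hr_drop_bpm = 0),
                               "saline")
  # no activation, no heart-rate drop: everything flat at baseline
  expect_equal(range(sal$bold$data), c(1000, 1000))
  expect_true(all(sal$truth$roi_amplitude_psc == 0))

  bad <- session_truth(roi_amplitude_psc = c(nonexistent = 1))
  expect_error(simulate_bold_session(atl, cfg, bad, "harmaline"),
               "absent from the atlas")
})

test_that("accelerometer sessions carry a 13 Hz tremor on a motion floor", {
  cfg <- quick_config()
  tr <- session_truth(tremor_amplitude_g = 2)
  acc <- simulate_accelerometer(cfg, tr, session_index = 1, seed = 5)
  expect_equal(acc$rate_hz, 100)
  expect_equal(acc$events$injection_s, 600)

  # spectral maximum above 2 Hz within +-1 bin (0.1 Hz) of the tremor
  # frequency, checked on a post-injection bin with the DFT oracle
  seg <- acc$samples[(900 * 100 + 1):(910 * 100)]
  spec <- dft_spectrum_oracle(seg, 100)
  sel <- spec$freq_hz > 2
  fpeak <- spec$freq_hz[sel][which.max(spec$amplitude[sel])]
  expect_lte(abs(fpeak - 13), 0.1 + 1e-9)

  expect_error(
    simulate_accelerometer(cfg, session_truth(tremor_freq_hz = 60), 1),
    "Nyquist")
  expect_error(simulate_accelerometer(cfg, tr, session_index = 99),
               "schedule")
})

test_that("zero-amplitude tremor leaves the post-injection spectrum at baseline", {
  cfg <- quick_config()
  tr <- session_truth(tremor_amplitude_g = 0)
  acc <- simulate_accelerometer(cfg, tr, session_index = 1, seed = 9)
  ser <- tremor_index_series(acc)
  nrm <- aggregate_and_normalize(ser, c(0, 600), window_s = 300)
  expect_true(all(abs(nrm$index - 1) < 0.25))
})

test_that("experiment bundles follow the session schedule with tolerance decay", {
  cfg <- quick_config(seed = 11)
  bun <- simulate_experiment(cfg, session_truth())
  kinds <- vapply(bun$animals[[1]], `[[`, "", "kind")
  expect_equal(sum(kinds == "fmri_harmaline"), 3L)
  expect_equal(sum(kinds == "fmri_saline"), 1L)
  expect_equal(sum(kinds == "behavior"), 3L)

  # the drug is injected at six of the seven sessions; the decay exponent
  # counts prior injections, so behavioural sessions are injections 2, 4, 6
  beh <- which(kinds == "behavior")
  expect_equal(vapply(bun$animals[[1]][beh], `[[`, 0L,
                      "n_prior_injections"), c(1L, 3L, 5L),
               ignore_attr = TRUE)
  # true tremor amplitude strictly decreasing across behaviour sessions
  amps <- vapply(bun$animals[[1]][beh],
                 function(r) r$truth$tremor_amplitude_g, 0)
  expect_true(all(diff(amps) < 0))
  # activation amplitude decays across harmaline scans too
  harm <- which(kinds == "fmri_harmaline")
  ion <- vapply(bun$animals[[1]][harm],
                function(r) r$truth$roi_amplitude_psc[["ION"]], 0)
  expect_true(all(diff(ion) < 0))
  # saline session truth is null
  sal <- which(kinds == "fmri_saline")
  expect_true(all(bun$animals[[1]][[sal]]$truth$roi_amplitude_psc == 0))

  expect_error(experiment_config(n_animals = 0), ">= 1")

  # determinism of the whole bundle
  bun2 <- simulate_experiment(cfg, session_truth())
  expect_identical(bun$animals[[1]][[1]]$bold$data,
                   bun2$animals[[1]][[1]]$bold$data)
  expect_identical(bun$animals[[1]][[beh[1]]]$accel$samples,
                   bun2$animals[[1]][[beh[1]]]$accel$samples)
})
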