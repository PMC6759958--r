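#' Experiment configuration
#'
#' Describes one simulated ph-fMRI tremor experiment. Defaults reproduce the
#' motivating protocol: 242-volume scans at TR 2 s (484 s total) with the
#' intravenous injection starting at t = 234 s over 40 s; per animal, three
#' harmaline fMRI scans alternating with three behavioural (accelerometer)
#' sessions at 72 h intervals, plus one saline control scan immediately after
#' the final harmaline scan; accelerometry at 100 Hz with a 30 min baseline
#' and 2 h post-injection monitoring.
#'
#' @param n_animals number of animals (default 5).
#' @param n_volumes volumes per scan (default 242).
#' @param tr_s repetition time, seconds (default 2).
#' @param injection_onset_s injection start within the scan, s (default 234).
#' @param injection_duration_s infusion duration, s (default 40).
#' @param session_schedule list of session descriptors, each a list with
#'   `kind` in `"fmri_harmaline"`, `"fmri_saline"`, `"behavior"` and
#'   `interval_h` (hours since the previous session). Default:
#'   [default_schedule()].
#' @param accel_rate_hz accelerometer sampling rate, Hz (default 100).
#' @param behavior_baseline_s baseline monitoring before injection, s
#'   (default 1800; scalable for quick simulations).
#' @param behavior_post_s post-injection monitoring, s (default 7200).
#' @param grid_shape simulation grid, voxels (default c(24, 24, 16)).
#' @param seed master seed for the hierarchical sub-seed scheme.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_animals = 5, n_volumes = 242, tr_s = 2,
                              injection_onset_s = 234,
                              injection_duration_s = 40,
                              session_schedule = default_schedule(),
                              accel_rate_hz = 100,
                              behavior_baseline_s = 1800,
                              behavior_post_s = 7200,
                              grid_shape = c(24, 24, 16),
                              seed = 1L) {
  if (n_animals < 1 || n_volumes < 1) stop("counts must be >= 1")
  if (tr_s <= 0 || accel_rate_hz <= 0) stop("rates must be positive")
  if (injection_onset_s + injection_duration_s >= n_volumes * tr_s)
    stop("injection must finish before the end of the scan")
  if (length(session_schedule) == 0) stop("session schedule must be non-empty")
  kinds <- vapply(session_schedule, `[[`, "", "kind")
  if (!all(kinds %in% c("fmri_harmaline", "fmri_saline", "behavior")))
    stop("unknown session kind in schedule")
  structure(list(n_animals = as.integer(n_animals),
                 n_volumes = as.integer(n_volumes), tr_s = tr_s,
                 injection_onset_s = injection_onset_s,
                 injection_duration_s = injection_duration_s,
                 session_schedule = session_schedule,
                 accel_rate_hz = accel_rate_hz,
                 behavior_baseline_s = behavior_baseline_s,
                 behavior_post_s = behavior_post_s,
                 grid_shape = as.integer(grid_shape),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @details `default_schedule()` returns the seven-session protocol:
#'   harmaline fMRI and behaviour alternating three times each (drug injected
#'   at every one of those six sessions, so tolerance accrues across all of
#'   them), with the saline control scan appended on the same day as the
#'   final harmaline scan.
#' @export
default_schedule <- function() {
  list(
    list(kind = "fmri_harmaline", interval_h = 0),
    list(kind = "behavior",       interval_h = 72),
    list(kind = "fmri_harmaline", interval_h = 72),
    list(kind = "behavior",       interval_h = 72),
    list(kind = "fmri_harmaline", interval_h = 72),
    list(kind = "fmri_saline",    interval_h = 0),
    list(kind = "behavior",       interval_h = 72)
  )
}

# number of harmaline injections delivered before schedule entry `i`
# (the drug is injected at every harmaline-fMRI and behaviour session)
injections_before <- function(schedule, i) {
  if (i <= 1) return(0L)
  kinds <- vapply(schedule[seq_len(i - 1)], `[[`, "", "kind")
  sum(kinds %in% c("fmri_harmaline", "behavior"))
}

#' Ground-truth parameters for one simulated session
#'
#' Houses everything the generator needs to manufacture a session and later
#' check recovery: per-ROI activation amplitudes (percent signal change),
#' cardiovascular-artifact gains, the heart-rate response, tremor parameters,
#' post-injection network coupling, and the across-session tolerance decay.
#'
#' Defaults are the package's stated world: ION and cerebellum at 1% PSC with
#' graded involvement elsewhere; a 40 bpm bradycardia from the 120 bpm
#' anaesthetised baseline reaching its nadir 600 s after injection; 13 Hz
#' tremor on a 0-10 Hz broadband motion floor; multiplicative tolerance decay
#' 0.7 per prior injection. The heart-rate drop amplitude is a free
#' parameter (the source data report the shape, not the depth).
#'
#' @param roi_amplitude_psc named numeric, ROI -> activation amplitude in %
#'   signal change.
#' @param response_block_s duration of the true neural response epoch
#'   modelled as a boxcar at injection onset, s (default 25).
#' @param artifact_gain named numeric, tissue class (`gray`, `white`) -> BOLD
#'   drift in % signal per 100% fractional heart-rate change.
#' @param hr_baseline_bpm,hr_drop_bpm,hr_time_to_nadir_s heart-rate response:
#'   pre-injection baseline, drop depth, and time from injection to nadir.
#' @param hr_tau_rise_s,hr_tau_recovery_s time constants of the decline and
#'   recovery limbs.
#' @param hr_noise_bpm measurement jitter on the recorded trace.
#' @param tremor_amplitude_g,tremor_freq_hz tremor oscillation peak amplitude
#'   (acceleration units) and frequency (default 13 Hz).
#' @param tremor_tau_rise_s,tremor_tau_decay_s tremor envelope rise/decay
#'   time constants.
#' @param motion_amplitude_g broadband (< 10 Hz) motion noise SD.
#' @param sensor_noise_g white sensor-noise SD (all frequencies).
#' @param bold_baseline mean BOLD level, arbitrary scanner units.
#' @param bold_noise_pct white BOLD noise SD, % of baseline (default 1,
#'   i.e. a temporal SNR of 100, typical of 3T EPI).
#' @param coupling data.frame (`roi_a`, `roi_b`, `strength`) of latent
#'   post-injection coupling factors added to both ROIs (raw signal units).
#' @param decay_factor multiplicative tolerance decay in (0, 1] applied per
#'   prior harmaline injection to activation, tremor and coupling.
#' @param seed session seed (overridden by [simulate_experiment()]).
#' @return an object of class `session_truth`.
#' @export
session_truth <- function(roi_amplitude_psc = c(ION = 1, cerebellum = 1,
                                                DCN = 0.8, thalamus = 0.6,
                                                SMC = 0.4, visual = 0.4,
                                                limbic = 0.2),
                          response_block_s = 25,
                          artifact_gain = c(gray = 6, white = 3),
                          hr_baseline_bpm = 120, hr_drop_bpm = 40,
                          hr_time_to_nadir_s = 600,
                          hr_tau_rise_s = 120, hr_tau_recovery_s = 300,
                          hr_noise_bpm = 1,
                          tremor_amplitude_g = 1, tremor_freq_hz = 13,
                          tremor_tau_rise_s = 60, tremor_tau_decay_s = 2400,
                          motion_amplitude_g = 1, sensor_noise_g = 0.05,
                          bold_baseline = 1000, bold_noise_pct = 1,
                          coupling = data.frame(
                            roi_a = c("cerebellum", "cerebellum"),
                            roi_b = c("thalamus", "DCN"),
                            strength = c(0.5, 0.4)),
                          decay_factor = 0.7, seed = 1L) {
  if (hr_baseline_bpm <= 0) stop("heart-rate baseline must be positive")
  if (hr_drop_bpm < 0) stop("heart-rate drop must be non-negative")
  if (hr_drop_bpm >= hr_baseline_bpm)
    stop("heart-rate drop >= baseline: bpm would reach zero")
  if (tremor_freq_hz <= 0) stop("tremor frequency must be positive")
  if (decay_factor <= 0 || decay_factor > 1)
    stop("decay factor must be in (0, 1]")
  structure(list(roi_amplitude_psc = roi_amplitude_psc,
                 response_block_s = response_block_s,
                 artifact_gain = artifact_gain,
                 hr_baseline_bpm = hr_baseline_bpm,
                 hr_drop_bpm = hr_drop_bpm,
                 hr_time_to_nadir_s = hr_time_to_nadir_s,
                 hr_tau_rise_s = hr_tau_rise_s,
                 hr_tau_recovery_s = hr_tau_recovery_s,
                 hr_noise_bpm = hr_noise_bpm,
                 tremor_amplitude_g = tremor_amplitude_g,
                 tremor_freq_hz = tremor_freq_hz,
                 tremor_tau_rise_s = tremor_tau_rise_s,
                 tremor_tau_decay_s = tremor_tau_decay_s,
                 motion_amplitude_g = motion_amplitude_g,
                 sensor_noise_g = sensor_noise_g,
                 bold_baseline = bold_baseline,
                 bold_noise_pct = bold_noise_pct,
                 coupling = coupling,
                 decay_factor = decay_factor,
                 seed = as.integer(seed)),
            class = "session_truth")
}

# truth with tolerance decay applied for the k-th-injection session
apply_decay <- function(truth, n_prior_injections) {
  f <- truth$decay_factor^n_prior_injections
  truth$roi_amplitude_psc <- truth$roi_amplitude_psc * f
  truth$tremor_amplitude_g <- truth$tremor_amplitude_g * f
  if (nrow(truth$coupling) > 0)
    truth$coupling$strength <- truth$coupling$strength * f
  truth
}

#' Build a block-ROI atlas volume
#'
#' Stand-in for a registered brain atlas: each named ROI is an axis-aligned
#' voxel block on a small grid. The default specification defines the six
#' network ROIs used in the connectivity analysis (SMC, thalamus, limbic,
#' cerebellum, DCN, visual) plus the ION for the activation analyses.
#'
#' @param grid_shape length-3 integer grid size.
#' @param roi_spec named list; each element is a 3x2 integer matrix of
#'   inclusive voxel ranges (rows = axes, columns = lo, hi). Blocks must be
#'   disjoint and lie within the grid.
#' @param voxel_size_mm voxel size, mm.
#' @return an [atlas_volume] with one label per ROI, in `roi_spec` order.
#' @examples
#' atl <- make_atlas()
#' names(atl$label_table)
#' @export
make_atlas <- function(grid_shape = c(24, 24, 16),
                       roi_spec = default_roi_spec(),
                       voxel_size_mm = c(1.7, 1.7, 2.4)) {
  if (length(roi_spec) == 0) stop("roi_spec must name at least one ROI")
  if (is.null(names(roi_spec)) || any(!nzchar(names(roi_spec))))
    stop("roi_spec must be a named list")
  labels <- array(0L, dim = grid_shape)
  for (i in seq_along(roi_spec)) {
    b <- roi_spec[[i]]
    if (!is.matrix(b) || !identical(dim(b), c(3L, 2L)))
      stop("each ROI block must be a 3x2 matrix of voxel ranges")
    if (any(b[, 1] < 1) || any(b[, 2] > grid_shape) || any(b[, 1] > b[, 2]))
      stop(sprintf("ROI '%s' block outside the grid", names(roi_spec)[i]))
    ix <- b[1, 1]:b[1, 2]; iy <- b[2, 1]:b[2, 2]; iz <- b[3, 1]:b[3, 2]
    if (any(labels[ix, iy, iz] != 0L))
      stop(sprintf("ROI '%s' overlaps a previously placed ROI",
                   names(roi_spec)[i]))
    labels[ix, iy, iz] <- i
  }
  atlas_volume(labels, voxel_size_mm = voxel_size_mm,
               label_table = setNames(seq_along(roi_spec), names(roi_spec)))
}

#' @rdname make_atlas
#' @export
default_roi_spec <- function() {
  blk <- function(x, y, z) matrix(c(x, y, z), nrow = 3, byrow = TRUE)
  list(
    SMC        = blk(c(3, 8),   c(17, 22), c(11, 14)),
    thalamus   = blk(c(10, 15), c(11, 15), c(8, 11)),
    limbic     = blk(c(10, 15), c(17, 22), c(10, 13)),
    cerebellum = blk(c(9, 16),  c(3, 8),   c(5, 9)),
    DCN        = blk(c(11, 14), c(9, 10),  c(5, 7)),
    visual     = blk(c(17, 22), c(17, 22), c(11, 14)),
    ION        = blk(c(12, 14), c(3, 5),   c(1, 3))
  )
}

# closed-form bradycardia trajectory: exponential decline to the nadir,
# exponential recovery after it; the rise term is frozen at the nadir and the
# shape normalised so the minimum is exactly baseline - drop at
# onset + t_nadir for any time constants
hr_trajectory <- function(t, onset_s, baseline, drop, t_nadir, tau1, tau2) {
  tp <- pmax(0, t - onset_s)
  g <- (1 - exp(-pmin(tp, t_nadir) / tau1)) *
    exp(-pmax(0, tp - t_nadir) / tau2)
  gmax <- 1 - exp(-t_nadir / tau1)
  baseline - drop * g / gmax
}

#' Simulate a drug-injection heart-rate trace
#'
#' Constant anaesthetised baseline before injection, then a smooth
#' piecewise-exponential bradycardia reaching exactly `baseline - drop` at
#' the configured time-to-nadir, followed by exponential recovery; small
#' Gaussian measurement jitter on top. Deterministic given the seed.
#'
#' @param config an [experiment_config()].
#' @param truth a [session_truth()].
#' @param seed RNG seed for measurement jitter (default `truth$seed`).
#' @param sample_rate_hz sampling rate of the returned trace (default 1 Hz).
#' @param duration_s trace duration (default the scan length).
#' @return data.frame with columns `time_s`, `value` (bpm).
#' @export
simulate_heart_rate <- function(config, truth, seed = truth$seed,
                                sample_rate_hz = 1,
                                duration_s = config$n_volumes * config$tr_s) {
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  hr <- hr_trajectory(t, config$injection_onset_s, truth$hr_baseline_bpm,
                      truth$hr_drop_bpm, truth$hr_time_to_nadir_s,
                      truth$hr_tau_rise_s, truth$hr_tau_recovery_s)
  if (truth$hr_noise_bpm > 0)
    hr <- hr + with_seed(seed, rnorm(length(t), sd = truth$hr_noise_bpm))
  data.frame(time_s = t, value = hr)
}

#' Simulate one BOLD fMRI session
#'
#' Each voxel series is assembled as
#' baseline level + activation + cardiovascular artifact + white noise:
#' the activation term is the ROI amplitude (% of baseline) times the
#' HRF-convolved injection-block regressor (peak 1); the artifact term is the
#' tissue-class gain times the fractional heart-rate deviation resampled to
#' volume onsets (gray matter inside ROIs, white matter elsewhere); optional
#' post-injection latent coupling factors are added to ROI pairs to create
#' drug-induced connectivity. Saline sessions force activation, heart-rate
#' drop and coupling to zero by construction.
#'
#' @param atlas an [atlas_volume] defining the grid and ROIs.
#' @param config an [experiment_config()].
#' @param truth a [session_truth()]; every ROI named in
#'   `truth$roi_amplitude_psc` must exist in the atlas.
#' @param condition `"harmaline"` or `"saline"`.
#' @param seed session seed (default `truth$seed`).
#' @return list with `bold` ([bold4d]), `hr` (the heart-rate trace used,
#'   data.frame), `regressor` (per-volume task regressor), `truth`,
#'   `condition`.
#' @export
simulate_bold_session <- function(atlas, config, truth,
                                  condition = c("harmaline", "saline"),
                                  seed = truth$seed) {
  condition <- match.arg(condition)
  amps <- truth$roi_amplitude_psc
  missing_rois <- setdiff(names(amps), names(atlas$label_table))
  if (length(missing_rois) > 0)
    stop(sprintf("truth names ROIs absent from the atlas: %s",
                 paste(missing_rois, collapse = ", ")))
  if (condition == "saline") {
    truth$hr_drop_bpm <- 0
    truth$roi_amplitude_psc[] <- 0
    amps <- truth$roi_amplitude_psc
    truth$coupling <- truth$coupling[0, ]
  }

  hr <- simulate_heart_rate(config, truth, seed = derive_seed(seed, 1))
  onsets <- (seq_len(config$n_volumes) - 1) * config$tr_s
  hr_at_vol <- approx(hr$time_s, hr$value, xout = onsets)$y
  hr_dev <- (hr_at_vol - truth$hr_baseline_bpm) / truth$hr_baseline_bpm

  reg <- task_regressor(config$n_volumes, config$tr_s,
                        config$injection_onset_s, truth$response_block_s)

  d <- dim(atlas$labels)
  nvox <- prod(d)
  base <- truth$bold_baseline
  # per-voxel artifact gain by tissue class: ROI voxels are "gray"
  gain <- ifelse(as.vector(atlas$labels) > 0,
                 truth$artifact_gain[["gray"]],
                 truth$artifact_gain[["white"]])
  # per-voxel activation amplitude (% of baseline)
  amp_vox <- numeric(nvox)
  for (roi in names(amps))
    amp_vox[as.vector(atlas$labels) == atlas$label_table[[roi]]] <- amps[[roi]]

  # volumes x voxels, built from outer products of the temporal components
  y <- tcrossprod(rep(base, config$n_volumes), rep(1, nvox)) +
    tcrossprod(reg, base * amp_vox / 100) +
    tcrossprod(hr_dev, base * gain / 100)

  if (nrow(truth$coupling) > 0) {
    post <- onsets >= config$injection_onset_s
    for (k in seq_len(nrow(truth$coupling))) {
      z <- with_seed(derive_seed(seed, 2, k),
                     rnorm(sum(post)))
      sel <- as.vector(atlas$labels) %in%
        atlas$label_table[c(truth$coupling$roi_a[k], truth$coupling$roi_b[k])]
      y[post, sel] <- y[post, sel] + truth$coupling$strength[k] * z
    }
  }

  if (truth$bold_noise_pct > 0) {
    y <- y + with_seed(derive_seed(seed, 3),
                       rnorm(length(y),
                             sd = base * truth$bold_noise_pct / 100))
  }

  bold <- bold4d(array(t(y), dim = c(d, config$n_volumes)),
                 tr_s = config$tr_s, voxel_size_mm = atlas$voxel_size_mm)
  list(bold = bold, hr = hr, regressor = reg, truth = truth,
       condition = condition)
}

#' Simulate a behavioural accelerometer session
#'
#' Baseline segment: broadband low-frequency (< 10 Hz) motion noise plus a
#' small white sensor-noise floor. After the injection a tremor oscillation
#' (default 13 Hz) is added, its envelope rising over ~1 min, persisting, and
#' decaying with the tremor time constant; the oscillation amplitude is
#' scaled by `decay_factor^(injections so far)` to emulate tolerance.
#'
#' @param config an [experiment_config()].
#' @param truth a [session_truth()].
#' @param session_index position of this session in the schedule (drives the
#'   tolerance exponent).
#' @param seed session seed (default `truth$seed`).
#' @return an [accel_trace] with the injection time in `events`.
#' @export
simulate_accelerometer <- function(config, truth, session_index = 1,
                                   seed = truth$seed) {
  if (session_index < 1 || session_index > length(config$session_schedule))
    stop("session_index outside the schedule")
  fs <- config$accel_rate_hz
  if (truth$tremor_freq_hz >= fs / 2)
    stop("tremor frequency must be below the Nyquist frequency")
  n_prior <- injections_before(config$session_schedule, session_index)
  amp <- truth$tremor_amplitude_g * truth$decay_factor^n_prior

  dur <- config$behavior_baseline_s + config$behavior_post_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  inj <- config$behavior_baseline_s

  samples <- with_seed(derive_seed(seed, 10), {
    motion <- lowpass_noise(n, fs, cutoff_hz = 10,
                            sd = truth$motion_amplitude_g)
    sensor <- rnorm(n, sd = truth$sensor_noise_g)
    phase <- runif(1, 0, 2 * pi)
    tp <- pmax(0, t - inj)
    env <- (1 - exp(-tp / truth$tremor_tau_rise_s)) *
      exp(-tp / truth$tremor_tau_decay_s)
    env[t < inj] <- 0
    tremor <- amp * env * sin(2 * pi * truth$tremor_freq_hz * tp + phase)
    motion + sensor + tremor
  })

  accel_trace(samples, rate_hz = fs, t0_s = 0,
              events = list(baseline_start_s = 0, injection_s = inj,
                            end_s = dur))
}

# white noise FFT-filtered to < cutoff_hz, rescaled to the requested SD
lowpass_noise <- function(n, fs, cutoff_hz, sd) {
  if (sd <= 0) return(numeric(n))
  w <- rnorm(n)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  spec <- fft(w)
  spec[abs(f) >= cutoff_hz] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Simulate a complete multi-session experiment
#'
#' Runs the full protocol for every animal: per schedule entry, a harmaline
#' or saline BOLD session (with its heart-rate trace) or a behavioural
#' accelerometer session. Tolerance decay is applied per prior harmaline
#' injection to activation amplitudes, tremor amplitude and network coupling.
#' All randomness derives from `config$seed` through the hierarchical
#' sub-seed scheme (animal -> session -> stream), so identical configurations
#' give bit-identical experiments. A saline session is generated with null
#' drug effects by construction.
#'
#' @param config an [experiment_config()].
#' @param truth a [session_truth()]: the session-1 (undecayed) ground truth.
#' @param atlas an [atlas_volume]; default [make_atlas()] on the config grid.
#' @param out_dir optional directory: when given, volumes are written as
#'   NIfTI (.nii.gz), traces as CSV and the ground-truth ledger as JSON.
#' @return list of class `experiment_bundle`: `config`, `atlas`, `truth`,
#'   and `animals` — per animal a list of session records, each with `kind`,
#'   `n_prior_injections`, the decayed `truth`, and the session data (`bold`
#'   + `hr`, or `accel`).
#' @export
simulate_experiment <- function(config, truth = session_truth(),
                                atlas = make_atlas(config$grid_shape),
                                out_dir = NULL) {
  if (config$n_animals < 1) stop("n_animals must be >= 1")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  animals <- vector("list", config$n_animals)
  names(animals) <- sprintf("animal%02d", seq_len(config$n_animals))
  ledger <- list()
  for (a in seq_len(config$n_animals)) {
    sessions <- vector("list", length(config$session_schedule))
    for (s in seq_along(config$session_schedule)) {
      kind <- config$session_schedule[[s]]$kind
      k <- injections_before(config$session_schedule, s)
      tr_s <- apply_decay(truth, k)
      sseed <- derive_seed(config$seed, a, s)
      rec <- list(kind = kind, n_prior_injections = k, truth = tr_s,
                  seed = sseed)
      if (kind == "behavior") {
        rec$accel <- simulate_accelerometer(config, tr_s, session_index = s,
                                            seed = sseed)
      } else {
        cond <- if (kind == "fmri_saline") "saline" else "harmaline"
        sim <- simulate_bold_session(atlas, config, tr_s, condition = cond,
                                     seed = sseed)
        rec$bold <- sim$bold
        rec$hr <- sim$hr
        rec$regressor <- sim$regressor
        rec$truth <- sim$truth # saline nulls applied
      }
      sessions[[s]] <- rec
      if (!is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("animal%02d_session%02d_%s",
                                           a, s, kind))
        if (kind == "behavior") {
          acc <- rec$accel
          write_trace(data.frame(
            time_s = acc$t0_s + (seq_along(acc$samples) - 1) / acc$rate_hz,
            value = acc$samples), paste0(stem, "_accel.csv"))
        } else {
          write_volume(rec$bold, paste0(stem, "_bold.nii.gz"))
          write_trace(rec$hr, paste0(stem, "_hr.csv"))
        }
        ledger[[sprintf("animal%02d", a)]][[sprintf("session%02d", s)]] <-
          list(kind = kind, n_prior_injections = k,
               roi_amplitude_psc = as.list(rec$truth$roi_amplitude_psc),
               tremor_amplitude_g = rec$truth$tremor_amplitude_g,
               hr_drop_bpm = rec$truth$hr_drop_bpm,
               seed = sseed)
      }
    }
    names(sessions) <- sprintf("session%02d", seq_along(sessions))
    animals[[a]] <- sessions
  }
  if (!is.null(out_dir)) {
    write_volume(atlas, file.path(out_dir, "atlas.nii.gz"))
    jsonlite::write_json(ledger, file.path(out_dir, "truth_ledger.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(config = config, atlas = atlas, truth = truth,
                 animals = animals),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  kinds <- vapply(x$config$session_schedule, `[[`, "", "kind")
  cat(sprintf("<experiment_bundle> %d animals x %d sessions (%s)\n",
              length(x$animals), length(kinds),
              paste(kinds, collapse = ", ")))
  invisible(x)
}
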