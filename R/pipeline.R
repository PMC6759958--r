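#' Run the full analysis pipeline on a simulated experiment
#'
#' Orchestrates the stages in protocol order — simulate (or ingest a
#' pre-built bundle), physiological-artifact correction, activation mapping
#' (optionally with a block-length sweep), tremor scoring, ROI connectivity,
#' and the beta-vs-tremor link — and returns a run manifest tying every
#' output to the configuration and seed. Two runs with the same config and
#' seed produce identical numeric outputs.
#'
#' Stage logic per session kind:
#' * fMRI sessions: heart-rate nuisance regression ([regress_nuisance()]),
#'   percent signal change over the pre-injection baseline, GLM beta/t maps
#'   ([fit_glm()]), group one-sample t with BH-FDR (q = 0.0005), per-session
#'   paired t vs the saline control (p < 0.005 uncorrected), and cluster
#'   peak tables.
#' * behavioural sessions: per-bin tremor index, 10-min aggregation with
#'   30-min-baseline normalisation, maximum index and duration, and the
#'   across-session trend statistics.
#' * connectivity: per fMRI session, pre/post epoch split (0-232 s /
#'   234-484 s), partial correlations, and the harmaline-post minus
#'   saline-post difference with permutation p-values.
#' * link: voxelwise regression of harmaline-session betas on the paired
#'   behavioural session's maximum tremor index.
#'
#' @param config an [experiment_config()].
#' @param truth a [session_truth()] for the generator.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "physio", "activate", "tremor", "connect", "link")`;
#'   later stages require the earlier ones they consume.
#' @param bundle optional pre-simulated `experiment_bundle` (skips the
#'   simulate stage).
#' @param sweep_lengths_s optional candidate block lengths for
#'   [block_length_sweep()] on the first animal's first harmaline session
#'   (NULL = no sweep).
#' @param block_length_s modelled response duration for the GLM (default 25).
#' @param q FDR rate for the group map (default 0.0005).
#' @param p_paired uncorrected threshold for the paired maps (default 0.005).
#' @param p_link uncorrected threshold for the tremor-link map (default
#'   0.05).
#' @param n_perm permutations for connectivity significance (default 2000;
#'   0 disables permutation p-values).
#' @param fwhm_mm spatial smoothing applied before the activation GLM, mm
#'   FWHM (default 2.8 per the published preprocessing; 0 disables).
#' @param min_cluster minimum cluster extent for peak tables (default 20).
#' @param out_dir optional directory for simulated files and result tables.
#' @return a `run_manifest` list: `config`, `seed`, `stages`, `results`
#'   (per-stage outputs incl. figure-analog tables), `version`, `log`.
#' @export
run_pipeline <- function(config, truth = session_truth(),
                         stages = c("simulate", "physio", "activate",
                                    "tremor", "connect", "link"),
                         bundle = NULL, sweep_lengths_s = NULL,
                         block_length_s = 25, q = 0.0005, p_paired = 0.005,
                         p_link = 0.05, n_perm = 2000, fwhm_mm = 2.8,
                         min_cluster = 20, out_dir = NULL) {
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  results <- list()

  if ("simulate" %in% stages && is.null(bundle)) {
    say("simulate: %d animals, seed %d", config$n_animals, config$seed)
    bundle <- simulate_experiment(config, truth, out_dir = out_dir)
  }
  if (is.null(bundle))
    stop("stage 'physio' is missing its input: no bundle (run 'simulate' or pass one)")
  atlas <- bundle$atlas
  kinds <- vapply(config$session_schedule, `[[`, "", "kind")
  fmri_idx <- which(kinds %in% c("fmri_harmaline", "fmri_saline"))
  harm_idx <- which(kinds == "fmri_harmaline")
  beh_idx <- which(kinds == "behavior")

  cleaned <- list() # [[animal]][[session]] residual bold
  hr_regs <- list() # matching per-volume heart-rate regressors
  if ("physio" %in% stages) {
    say("physio: heart-rate nuisance regression on %d fMRI sessions/animal",
        length(fmri_idx))
    for (a in seq_along(bundle$animals)) {
      cleaned[[a]] <- list()
      hr_regs[[a]] <- list()
      for (s in fmri_idx) {
        rec <- bundle$animals[[a]][[s]]
        reg <- resample_to_volumes(rec$hr, config$n_volumes, config$tr_s)
        des <- nuisance_design(reg)
        hr_regs[[a]][[as.character(s)]] <- reg
        cleaned[[a]][[as.character(s)]] <-
          regress_nuisance(rec$bold, des)$residual
      }
    }
  }

  betas <- list() # [[animal]][[session char]] beta stat_map (PSC units)
  if ("activate" %in% stages) {
    if (length(cleaned) == 0)
      stop("stage 'activate' is missing its input: run 'physio' first")
    base_vols <- which((seq_len(config$n_volumes) - 1) * config$tr_s <
                         config$injection_onset_s)
    if (!is.null(sweep_lengths_s)) {
      s1 <- as.character(harm_idx[1])
      sw <- block_length_sweep(cleaned[[1]][[s1]],
                               sweep_lengths_s, roi_mask(atlas, "ION"),
                               onset_s = config$injection_onset_s,
                               nuisance = cbind(hr = hr_regs[[1]][[s1]]))
      results$sweep <- sw
      block_length_s <- sw$best_length_s
      say("activate: sweep selected block length %g s", block_length_s)
    }
    for (a in seq_along(cleaned)) {
      betas[[a]] <- list()
      for (s in fmri_idx) {
        sess <- cleaned[[a]][[as.character(s)]]
        if (fwhm_mm > 0) sess <- smooth_gaussian(sess, fwhm_mm)
        psc <- percent_signal_change(sess, base_vols)
        # the session's HR regressor rides along in the design so the task
        # beta is estimated jointly with the cardiovascular artifact
        des <- build_design(config$n_volumes, config$tr_s,
                            onset_s = config$injection_onset_s,
                            block_length_s = block_length_s,
                            nuisance = cbind(hr = hr_regs[[a]][[as.character(s)]]))
        betas[[a]][[as.character(s)]] <- fit_glm(psc, des)$beta
      }
    }
    # group map: all harmaline-session betas across the experiment
    harm_betas <- unlist(lapply(betas, function(x) x[as.character(harm_idx)]),
                         recursive = FALSE)
    grp <- group_one_sample_t(harm_betas)
    fdr <- fdr_threshold(grp$p, q = q)
    # t threshold implied by the FDR rejection set; above the map maximum
    # (empty peak table) when nothing survives
    tthr <- if (fdr$n_rejected > 0)
      min(abs(grp$t$values[fdr$mask])) else max(grp$t$values) + 1
    results$group <- list(t = grp$t, p = grp$p, fdr = fdr,
                          peaks = cluster_peaks(grp$t, threshold = tthr,
                                                min_cluster = min_cluster,
                                                atlas = atlas))
    # per-session paired maps vs saline
    sal_betas <- lapply(betas, function(x) x[[as.character(fmri_idx[
      kinds[fmri_idx] == "fmri_saline"][1])]])
    results$paired <- lapply(harm_idx, function(s) {
      hb <- lapply(betas, `[[`, as.character(s))
      pt <- paired_t(hb, sal_betas)
      crit <- stats::qt(1 - p_paired / 2, df = pt$t$df)
      list(session = s, t = pt$t, p = pt$p,
           peaks = cluster_peaks(pt$t, threshold = crit,
                                 min_cluster = min_cluster, atlas = atlas))
    })
    say("activate: group map %d voxels at q < %g; %d paired maps at p < %g",
        results$group$fdr$n_rejected, q, length(harm_idx), p_paired)
  }

  tremor_tab <- NULL
  if ("tremor" %in% stages) {
    base_win <- c(0, config$behavior_baseline_s)
    agg_win <- min(600, config$behavior_baseline_s)
    rows <- list()
    norm_series <- list()
    for (a in seq_along(bundle$animals)) {
      norm_series[[a]] <- list()
      for (s in beh_idx) {
        acc <- bundle$animals[[a]][[s]]$accel
        ser <- tremor_index_series(acc)
        nrm <- aggregate_and_normalize(ser, base_win, window_s = agg_win)
        norm_series[[a]][[as.character(s)]] <- nrm
        rows[[length(rows) + 1]] <- data.frame(
          animal = a, session = s,
          max_index = max_tremor_index(nrm),
          duration_s = tremor_duration(nrm))
      }
    }
    tremor_tab <- do.call(rbind, rows)
    max_mat <- matrix(tremor_tab$max_index, nrow = length(bundle$animals),
                      byrow = TRUE)
    dur_mat <- matrix(tremor_tab$duration_s, nrow = length(bundle$animals),
                      byrow = TRUE)
    results$tremor <- list(table = tremor_tab, series = norm_series,
                           trend = if (length(beh_idx) >= 2 &&
                                       length(bundle$animals) >= 2)
                             session_trend_stats(max_mat, dur_mat) else NULL)
    say("tremor: %d behavioural sessions scored", nrow(tremor_tab))
  }

  if ("connect" %in% stages) {
    if (length(cleaned) == 0)
      stop("stage 'connect' is missing its input: run 'physio' first")
    net_rois <- setdiff(names(atlas$label_table), "ION")
    scan_end <- config$n_volumes * config$tr_s
    pre_s <- c(0, config$injection_onset_s - config$tr_s)
    post_s <- c(config$injection_onset_s, scan_end)
    sal_s <- fmri_idx[kinds[fmri_idx] == "fmri_saline"][1]
    conn <- list()
    for (s in harm_idx) {
      deltas <- list()
      pvals <- list()
      for (a in seq_along(cleaned)) {
        ser_h <- roi_mean_series(cleaned[[a]][[as.character(s)]], atlas,
                                 net_rois)
        ser_s <- roi_mean_series(cleaned[[a]][[as.character(sal_s)]], atlas,
                                 net_rois)
        ep_h <- split_epochs(ser_h, pre_s, post_s)
        ep_s <- split_epochs(ser_s, pre_s, post_s)
        pc <- list(hp = partial_correlation(ep_h$pre),
                   hq = partial_correlation(ep_h$post, n_perm = n_perm,
                                            seed = derive_seed(config$seed,
                                                               a, s, 7)),
                   sp = partial_correlation(ep_s$pre),
                   sq = partial_correlation(ep_s$post))
        deltas[[a]] <- connectivity_change(pc$hp, pc$hq, pc$sp, pc$sq)$delta
        if (n_perm > 0) pvals[[a]] <- pc$hq$p_values
      }
      conn[[as.character(s)]] <- list(
        session = s,
        delta = Reduce(`+`, deltas) / length(deltas),
        p_values = if (n_perm > 0) pvals else NULL)
    }
    results$connectivity <- conn
    say("connect: %d harmaline sessions, %d ROIs, n_perm %d",
        length(harm_idx), length(net_rois), n_perm)
  }

  if ("link" %in% stages) {
    if (length(betas) == 0)
      stop("stage 'link' is missing its input: run 'activate' first")
    if (is.null(tremor_tab))
      stop("stage 'link' is missing its input: run 'tremor' first")
    # pairing rule: k-th harmaline fMRI session <-> k-th behavioural session
    obs_beta <- list(); obs_trem <- numeric()
    for (a in seq_along(betas)) {
      for (k in seq_along(harm_idx)) {
        if (k > length(beh_idx)) next
        obs_beta[[length(obs_beta) + 1]] <-
          betas[[a]][[as.character(harm_idx[k])]]
        obs_trem <- c(obs_trem,
                      tremor_tab$max_index[tremor_tab$animal == a &
                                             tremor_tab$session ==
                                               beh_idx[k]])
      }
    }
    lk <- regress_beta_on_tremor(obs_beta, obs_trem)
    results$link <- list(slope = lk$slope, t = lk$t, p = lk$p,
                         enrichment = roi_enrichment(
                           lk$p, atlas, c("ION", "cerebellum"),
                           p_threshold = p_link, positive_only = lk$slope))
    say("link: %d observations, p < %g", length(obs_trem), p_link)
  }

  manifest <- structure(list(
    config = config, seed = config$seed, stages = stages,
    parameters = list(block_length_s = block_length_s, q = q,
                      p_paired = p_paired, p_link = p_link,
                      n_perm = n_perm, fwhm_mm = fwhm_mm,
                      min_cluster = min_cluster),
    results = results,
    version = as.character(utils::packageVersion("phtremor")),
    log = log_lines), class = "run_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(manifest, out_dir)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> phtremor", x$version, "\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Write the figure-analog summary tables of a run
#'
#' Renders the manifest's tables as delimited text: cluster peak tables
#' (group and per-session paired maps), the tremor summary and trend table,
#' and the connectivity difference matrices with their significance masks.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_report <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  r <- manifest$results
  if (!is.null(r$group)) put(r$group$peaks, "group_peaks.tsv")
  if (!is.null(r$paired))
    for (pp in r$paired)
      put(pp$peaks, sprintf("paired_peaks_session%02d.tsv", pp$session))
  if (!is.null(r$tremor)) {
    put(r$tremor$table, "tremor_summary.tsv")
    if (!is.null(r$tremor$trend)) put(r$tremor$trend$pairwise,
                                      "tremor_trend_pairwise.tsv")
  }
  if (!is.null(r$connectivity)) {
    for (cc in r$connectivity) {
      dm <- as.data.frame(cc$delta)
      dm <- cbind(roi = rownames(cc$delta), dm)
      put(dm, sprintf("connectivity_delta_session%02d.tsv", cc$session))
    }
  }
  if (!is.null(r$sweep)) put(r$sweep$table, "block_length_sweep.tsv")
  if (!is.null(r$link))
    put(data.frame(odds_ratio = r$link$enrichment$odds_ratio),
        "link_enrichment.tsv")
  jsonlite::write_json(
    list(seed = manifest$seed, version = manifest$version,
         parameters = manifest$parameters, log = manifest$log),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(out_dir, "manifest.json")))
}
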