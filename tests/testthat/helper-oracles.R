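# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own FFT/linear-algebra paths.

# direct DFT amplitude spectrum with a Hann window, matching the package's
# scaling convention (2|X_k|/sum(w) single-sided, |X_0|/sum(w) at DC)
dft_spectrum_oracle <- function(segment, rate_hz) {
  n <- length(segment)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xw <- segment * w
  half <- floor(n / 2)
  ks <- 0:half
  amp <- vapply(ks, function(k) {
    ph <- -2 * pi * k * (seq_len(n) - 1) / n
    Mod(sum(complex(real = xw * cos(ph), imaginary = xw * sin(ph))))
  }, numeric(1)) / sum(w)
  amp[ks > 0 & ks < n - half] <- 2 * amp[ks > 0 & ks < n - half]
  data.frame(freq_hz = ks * rate_hz / n, amplitude = amp)
}

# band mean with the package's half-open [lo, hi) convention, DC excluded
band_mean_oracle <- function(spec, lo, hi) {
  sel <- spec$freq_hz >= lo - 1e-9 & spec$freq_hz < hi - 1e-9 &
    spec$freq_hz > 1e-9
  mean(spec$amplitude[sel])
}

# per-bin tremor index straight from the DFT oracle
tremor_index_oracle <- function(samples, rate_hz, bin_width_s = 10) {
  nper <- round(bin_width_s * rate_hz)
  nb <- floor(length(samples) / nper)
  vapply(seq_len(nb), function(b) {
    spec <- dft_spectrum_oracle(samples[((b - 1) * nper + 1):(b * nper)],
                                rate_hz)
    band_mean_oracle(spec, 10, 16) / band_mean_oracle(spec, 0, 10)
  }, numeric(1))
}

# partial correlation by explicit residualisation: correlate the residuals
# of lm() fits of rows i and j on all remaining rows
pcor_residualization_oracle <- function(M) {
  k <- nrow(M)
  R <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    others <- t(M[-c(i, j), , drop = FALSE])
    ri <- stats::residuals(stats::lm(M[i, ] ~ others))
    rj <- stats::residuals(stats::lm(M[j, ] ~ others))
    R[i, j] <- R[j, i] <- stats::cor(ri, rj)
  }
  dimnames(R) <- list(rownames(M), rownames(M))
  R
}

# exhaustive Benjamini-Hochberg: largest k with p_(k) <= qk/m, reject all
# p <= p_(k)
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= q * seq_len(m) / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# exhaustive 26-connectivity labelling by repeated neighbourhood expansion
label_components_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  coords <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    lab[v[1], v[2], v[3]] <- nxt
    repeat {
      changed <- FALSE
      cur <- which(lab == nxt, arr.ind = TRUE)
      for (q in seq_len(nrow(cur))) {
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          w <- cur[q, ] + c(dx, dy, dz)
          if (any(w < 1) || any(w > d)) next
          if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
            lab[w[1], w[2], w[3]] <- nxt
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  lab
}

# sample n rows from a multivariate normal with covariance Sigma
rmvn <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(rnorm(n * nrow(Sigma)), n) %*% L
}

# small, quick experiment configurations for tests (overridable defaults)
quick_config <- function(...) {
  args <- utils::modifyList(list(n_animals = 1, behavior_baseline_s = 600,
                                 behavior_post_s = 1200), list(...))
  do.call(experiment_config, args)
}

quiet_truth <- function(...) {
  # noiseless, artifact-free truth for exact-construction checks
  args <- utils::modifyList(
    list(bold_noise_pct = 0, hr_noise_bpm = 0, hr_drop_bpm = 0,
         coupling = data.frame(roi_a = character(), roi_b = character(),
                               strength = numeric())),
    list(...))
  do.call(session_truth, args)
}
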