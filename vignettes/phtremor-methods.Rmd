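---
title: "Methods: pharmacological fMRI analysis of drug-induced tremor"
author: "phtremor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacological fMRI analysis of drug-induced tremor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind each stage. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The experiment being modelled

A tremorgenic beta-carboline (harmaline) is injected intravenously during
BOLD fMRI in anaesthetised large animals. Each animal undergoes alternating
drug-fMRI and awake behavioural (accelerometer) sessions at 72 h intervals,
with a saline control scan after the final drug scan. Three phenomena drive
the analysis design:

1. the drug evokes regional BOLD activation in the olivo-cerebello-
   thalamo-cortical circuit, time-locked to the injection;
2. it simultaneously evokes a profound bradycardia whose vascular
   consequences contaminate the global BOLD signal — a confound that must be
   removed before any activation claim;
3. repeated administration attenuates all drug effects ("tolerance"),
   which the analysis must be able to resolve across sessions.

## The synthetic-data generator

`simulate_experiment()` manufactures complete experiments with known ground
truth. Its defaults *are* the stated experimental world: 242 volumes at
TR 2 s (484 s), injection onset 234 s with a 40 s infusion, heart rate
baseline 120 bpm, accelerometry at 100 Hz with a 30 min baseline and 2 h
post-injection window, and seven sessions per animal (3 drug scans, 3
behavioural sessions, 1 saline scan; the drug is injected at six of them,
so the tolerance exponent of the k-th session counts all prior injections).

Per voxel, a BOLD series is

    y(t) = B + B·(a_r/100)·x(t) + B·(g_c/100)·h(t) + ε(t)

where `B` is the baseline level (1000 a.u.), `a_r` the ROI's activation
amplitude in percent signal change, `x(t)` the HRF-convolved injection
block (peak 1), `g_c` a tissue-class artifact gain (gray 6, white 3, in %
signal per 100 % fractional heart-rate change), `h(t)` the fractional
heart-rate deviation resampled to volume onsets, and `ε` white Gaussian
noise with SD 1 % of baseline (temporal SNR 100, typical of 3T EPI).
Defaults place 1 % PSC in ION and cerebellum with graded involvement
elsewhere. Post-injection latent factors (amplitude 0.5 and 0.4 a.u.)
couple cerebellum–thalamus and cerebellum–DCN to create drug-induced
connectivity. A saline session zeroes activation, heart-rate drop and
coupling by construction.

The heart-rate response is piecewise exponential: decline toward the nadir
with time constant τ₁ = 120 s, recovery with τ₂ = 300 s, normalised so the
minimum equals exactly `baseline − drop` at the configured time-to-nadir
(600 s after injection). The source observations constrain the *shape*
(immediate fall, nadir near 10 min, slow recovery) but not the depth, so
the 40 bpm default drop is a free parameter of the generator.

The accelerometer signal is broadband sub-10 Hz motion (FFT-filtered white
noise), a small white sensor floor, and after the injection a 13 Hz
sinusoid whose envelope rises over ~1 min and decays with a 40 min time
constant, scaled by `decay^(prior injections)` (decay 0.7).

All randomness flows from one master seed through a deterministic
hierarchical hash (`derive_seed(seed, animal, session, stream)`), so equal
configurations give bit-identical experiments.

**What the generator does not emulate.** No scanner physics, motion, spike
artifacts or temporal autocorrelation (noise is white); ROIs are labelled
blocks, not anatomy; the accelerometer is a single magnitude channel; the
drug response has one shared temporal shape across ROIs. A green
recovery test therefore establishes the correctness of the estimators
under the stated statistical structure — not robustness to structured
noise, motion or registration error.

## Physiological artifact correction

`regress_nuisance()` fits, per voxel, ordinary least squares on intercept,
centred linear drift and the centred/scaled heart-rate waveform
(`resample_to_volumes()`, linear interpolation at volume onsets), and
returns the series minus the non-intercept fit — the cleaned trace keeps
its mean level so percent signal change remains meaningful downstream.
Residuals are exactly orthogonal to every centred nuisance column and the
operation is idempotent.

Because the bradycardia and the injection block overlap in time, the HR
waveform shares variance with the task regressor. Sequential projection
(clean first, then fit the task) would attenuate the task beta by that
shared fraction, so the activation GLM carries the same HR column as an
extra nuisance regressor (`build_design(nuisance = )`). By the
Frisch–Waugh theorem this equals joint estimation on the raw data and is
unbiased; the parameter-recovery acceptance test checks exactly this.
The waveform is used unlagged by default (the recorded drift is only
slightly delayed, and the published analysis applies the waveform
directly); an integer-volume lag and the centring/scaling of the
regressor are exposed as options.

## Activation mapping

The HRF is the canonical double gamma (peak delay 5 s, undershoot delay
15 s, ratio 1/6, unit dispersions) — the pig HRF is uncharacterised, so
human-canonical defaults are used and exposed. The task regressor is a
boxcar of block length L starting at the injection onset, convolved on a
0.1 s grid, sampled at volume onsets, forced to zero before onset (the
FFT convolution otherwise leaves ~1e-16 ringing) and peak-normalised, so
betas are in the units of the data (PSC when fitted on PSC series).

The modelled "block length" is the duration of the neural response epoch.
It is selected by `block_length_sweep()`: per candidate L, fit the GLM and
score mean t over the ION mask (the presumed tremor pacemaker); the argmax
is chosen, ties toward the shortest candidate (the most conservative
model). Mean t was chosen over peak t or suprathreshold count because it is
the least sensitive to single-voxel noise; the alternatives are options.

Group inference is a voxelwise one-sample t across sessions' beta maps with
Benjamini–Hochberg FDR at q = 0.0005; per-session maps are paired t against
the saline control at uncorrected p < 0.005. All p-values are two-sided
(sidedness is unstated in the source; two-sided is conservative). Voxels
with numerically zero residual variance are flagged degenerate and report
t = 0 rather than ±Inf. Spatial smoothing is separable Gaussian convolution
with σ = FWHM/√(8 ln 2) per axis (FWHM 2.8 mm), zero-padded at the
boundary; `run_pipeline()` smooths after artifact correction, before the
GLM. Cluster tables use 26-connectivity components above the map's FDR- or
p-implied t threshold, a 20-voxel minimum extent, coordinates in mm from
the volume centre (one decimal), and hemisphere from the sign of x
(positive x reported as left, matching the source tables' convention).

With the generator defaults, the *group* map at q = 0.0005 is typically
empty: tolerance decay makes the true beta differ across sessions, which
enters the one-sample t as between-session variance and caps the group t
well below so strict a threshold at n = 15 maps. The per-session paired
maps, which do not pool across the decay, show the expected clusters. This
is a property of the stated world, not of the estimator; the acceptance
tests therefore validate amplitude recovery and false-positive calibration
rather than group-map counts.

## Tremor index

Each 10-s bin of the accelerometer trace is Hann-windowed and Fourier
transformed; amplitudes are single-sided and scaled by the window's
coherent gain, so a unit sinusoid on a bin centre reads amplitude 1. The
tremor index is the mean amplitude over 10–16 Hz divided by the mean over
0–10 Hz. Numerical conventions: bands are half-open `[lo, hi)` so the
10 Hz bin belongs to the tremor band only (the two published band
descriptions overlap at 10 Hz), and the DC bin is excluded from the motion
band because a constant offset is gravity, not motion. Bins are
non-overlapping and aligned to the baseline start. The index is
dimensionless, invariant to rescaling the trace, and strictly increasing
in tremor-band amplitude at a fixed floor — all verified against a direct
DFT oracle.

For session summaries the per-bin indices are averaged over 10-min windows
and normalised by the mean index of the 30-min baseline. The maximum
post-injection window is the per-session severity score. Tremor *duration*
has no published criterion; the package's stand-in rule is the length of
the longest contiguous run of post-injection windows above baseline mean +
2·SD (configurable `k`), which behaves monotonically under the generator's
envelope decay. Tolerance statistics are pairwise paired t-tests on the
maxima and a one-way ANOVA on the durations.

Whether the published "amplitude" denotes the amplitude or power spectrum
is ambiguous in the source; amplitude is the default and `use_power = TRUE`
is exposed.

## ROI connectivity

ROI-mean series (unweighted voxel means) are split into a pre-injection
epoch (onsets 0–232 s inclusive, 117 volumes at TR 2) and a post-injection
epoch (onsets in [234, 484) s, 125 volumes). Partial correlations come from
the inverse sample covariance, ρ_ij·rest = −P_ij/√(P_ii·P_jj), with rows
demeaned within the epoch only (no leakage of the other epoch's mean); a
residualisation implementation must and does agree to 1e-10, and a ridge of
1e-8·trace/n is applied with a warning if the covariance is singular.

The primary drug-specific contrast is PC(drug post) − PC(saline post);
post-minus-pre differences per condition are also returned, since the
source describes both operations without stating which composes its
figures. Significance is by permutation: one ROI's samples are shuffled
(simple shuffling, as described — no block permutation), the cell's partial
correlation recomputed n = 2000 times, and p = (1 + #{|null| ≥
|obs|})/(n + 1) — the add-one convention keeps p > 0 with minimum
1/(n + 1).

One structural caveat: a drug response with a shared temporal shape is a
rank-1 common factor across ROIs, and partialling on other ROIs does not
remove a latent factor (each ROI is factor + noise). Post-injection partial
correlations therefore contain a response-coherence component in addition
to the configured coupling; both decay with tolerance, which is the
behaviour the network acceptance test checks. Real data temper this by
regionally heterogeneous response shapes.

## Tremor–BOLD link

Beta maps from drug scans are paired with the interleaved behavioural
sessions (scan k ↔ behavioural session k) and pooled across animals and
sessions; per voxel, a simple linear regression of beta on maximum tremor
index reports slope, t (df = n − 2) and two-sided p, thresholded at
uncorrected p < 0.05. No animal random effect is fitted (n is far too
small; the source uses plain regression); a per-animal analysis is
possible by subsetting the observations. Enrichment of suprathreshold,
positive-slope voxels in ION/cerebellum is summarised as an odds ratio
with a 0.5 continuity correction when a cell is empty.

## Formats and reproducibility

Volumes travel as NIfTI-1 (.nii/.nii.gz) through a self-contained codec
(float64 data, voxel size in pixdim[2:4], TR in pixdim[5]; int32 labels) —
written because no NIfTI package is available in the supported
environment; traces as 2-column delimited text with a strictly increasing
time column; the truth ledger and run manifest as JSON. Every pipeline run
is reproducible bit-for-bit from (configuration, seed).
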