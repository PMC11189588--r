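---
title: "Avalanche dynamics as classification features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avalanche dynamics as classification features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(avalanchr)
```

## The problem

Resting-state electrophysiology carries diagnostic information about
conditions, such as temporal lobe epilepsy, that reorganize large-scale
brain dynamics. Classical functional-connectivity features (coherence-family
measures) assume stationarity and summarise power covariation. An
alternative is to describe the *aperiodic* part of the signal: brief
system-wide bursts of activity ("neuronal avalanches") whose spreading
pattern across regions is itself a network. This package implements that
workflow end to end for source-reconstructed ROI time series: avalanche
detection, branching-ratio diagnostics, avalanche transition matrices
(ATMs), an imaginary-coherence (ImCoh) comparison feature, SVM
classification of subjects from edge features, coefficient-based feature
importance, and the dependence of classification on recording length. A
branching-process simulator with known ground truth makes every stage
testable without clinical data, which are typically private.

## Avalanche model

Each ROI's series is z-scored over the full recording and binarized:
a sample is *active* when |z| exceeds a threshold (default 2.0; grids of
1.2–3.0 are scanned by `optimize_avalanche_params()`). Both signs count:
excursions are deviations from baseline regardless of polarity.
Z-scores are computed over the full concatenated recording rather than per
segment — a single scale per ROI keeps thresholds comparable across
segments, and per-segment scaling would let artifact-removal boundaries
modulate detection.

An avalanche is a maximal run of contiguous bins in which at least one ROI
is active, bounded by fully silent bins. Recordings may contain
discontinuities (upstream artifact-epoch removal); avalanches never cross a
segment boundary, and runs touching a segment edge are discarded as
incomplete, because a truncated avalanche would bias both the branching
ratio and the ATM. Runs shorter than `min_duration_bins` (default 2, grids
of 2–8 scanned) are discarded after binning.

The branching ratio of avalanche *i* with per-bin activation counts
\(n_j\), \(j = 1..N\), is the geometric mean of successive
descendant/ancestor ratios,
\[
\sigma_i = \prod_{j=1}^{N-1}\Big(\frac{n_{j+1}}{n_j}\Big)^{1/(N-1)}
         = \Big(\frac{n_N}{n_1}\Big)^{1/(N-1)},
\]
and the cohort value is the geometric mean over avalanches of duration at
least two bins. \(\sigma \approx 1\) marks critical cascade dynamics;
`select_bin_size()` picks the time bin whose \(\sigma\) is closest to 1
(ties to the smaller bin). Note the telescoping: \(\sigma_i\) depends only
on the first and last bin counts. One practical consequence, verified by
simulation here, is that moderate re-binning barely moves \(\sigma\) on
critical data, so bin selection between adjacent small bins can be
seed-sensitive; the selection rule itself is deterministic.

The ATM entry (i, j) is the probability that region j is active one lag
\(\delta\) (default 1 bin, 4 ms at 250 Hz) after region i, given i active,
estimated *within* each avalanche as a conditional frequency
(co-activations over ancestor bins) and then averaged element-wise across
avalanches. Rows of never-ancestor ROIs are zero rather than missing so the
feature space has a fixed dimension. Whether per-avalanche matrices should
be ancestor-normalized conditionals or binary occurrence indicators before
averaging is genuinely open; the conditional reading is the default and the
binary one is available via `normalization = "binary"`.

## Imaginary coherence

The comparison feature is the imaginary part of coherency,
\[
\mathrm{ImCoh}_{xy}(f) = \frac{\mathrm{Im}\,S_{xy}(f)}
                              {\sqrt{S_{xx}(f)\,S_{yy}(f)}},
\]
insensitive to zero-lag mixing and hence to volume-conduction-like leakage.
Cross-spectra are DPSS multitaper estimates over 10 s windows with 50%
overlap at 0.1 Hz native resolution (no zero padding; the native grid of a
10 s window already meets the resolution). The time-bandwidth product
defaults to NW = 2.5 with 2NW − 1 = 4 tapers, a standard
variance/bandwidth trade-off at this window length. Windows never straddle
segment boundaries. The band value is the unweighted mean over grid
frequencies of |ImCoh| (magnitude, because the sign only encodes arbitrary
lead/lag orientation; a signed variant exists behind `signed = TRUE`).
`imcoh_null_threshold()` provides a circular-shift surrogate null for
calibrating observed values.

## Classification

Subject-level feature vectors are all \(n(n-1)\) ordered off-diagonal ATM
entries (directed) or the \(n(n-1)/2\) upper-triangle ImCoh entries
(undirected), in a deterministic column-major order with labels
`"a->b"` / `"a--b"`. Evaluation uses 50 stratified shuffle splits with an
80/20 subject-level partition: features are z-scored with training-set
statistics only (standardization is not described in every published
pipeline but is required for comparable edge coefficients and stable
margins — a documented choice here); kernel (linear or RBF) and C (ladder
1e-2…1e2) are chosen per split by a stratified 5-fold cross-validated grid
search on the training portion (ties prefer linear, then smaller C); six
metrics (accuracy, ROC AUC, F1, precision, sensitivity, specificity) plus
the ROC curve are computed on the held-out subjects. Splits are stratified
by group because with ~30 subjects per group an unstratified 20% test set
can be single-class. All pseudo-randomness flows from one integer seed;
identical seeds give identical reports.

Edge importance is the median over splits of the absolute linear-SVM
coefficients; splits where the grid chose the RBF kernel have no
per-feature coefficients and are excluded (reported via a message). Node
importance is the arithmetic mean over incident edges, both directions for
ATMs. `optimize_avalanche_params()` scans the threshold/min-duration grid
and by default judges a pair by mean *inner-CV* accuracy (`mode =
"nested"`); judging by held-out accuracy (`mode = "test"`) reproduces the
simpler published practice but is optimistic when the winning pair's score
is then quoted as the performance, so the full grid is always returned for
audit. Ties prefer the higher threshold (stricter events), then the
shorter minimal duration.

## Signal-length analysis

`window_accuracy()` asks how much recording the ATM features need: for each
length (5–300 s) and each of `n_placements` random placements, ATMs are
rebuilt from that window alone and the full classification repeats; each
split records its median accuracy over placements. Windows are drawn
uniformly within a single recording segment, independently per subject (the
alternative — sharing placements across subjects — is equally defensible
but couples subjects through the window position). Binarization reuses the
full-recording z-scores, matching the main pipeline's definition of an
excursion; thus a window selects avalanches, it does not redefine the
baseline. Threshold and duration parameters stay fixed across lengths so
the time-scale effect is not confounded with re-optimization.

## The synthetic cohort generator

`make_cohort()` emulates the study conditions the package targets: two
groups of 30 subjects, 68 cortical ROIs at 250 Hz, 300 s of artifact-free
signal each. Dynamics are a discrete branching process on a random directed
graph P: while silent, each ROI seeds with `drive_rate`; an active ROI
recruits ROI j one bin later with probability \(P_{ij}\), parents combining
by noisy-OR; one refractory bin prevents frozen always-on states. Nonzero
weights are uniform (0.5–1.5 before scaling) and rescaled so active-row
sums average `target_rho`, the expected descendants per ancestor
(criticality at 1). Group B uses a copy of group A's graph with an
`effect_size` fraction of edges moved to previously empty slots, weights
preserved — so overall excitability and spectra are matched and the group
difference lives purely in *where* avalanches travel, the quantity ATMs
summarise and power-based connectivity does not.

Defaults were fixed once, by design, at density 0.5, drive 0.01,
one refractory bin:

* drive 0.01 keeps avalanche onsets small. The telescoped \(\sigma_i\)
  forces values ≥ 1 whenever an avalanche starts from a single seed (the
  last bin has at least one event), while heavy seeding biases \(\sigma\)
  down through small dying last bins; 0.01 balances the two so the critical
  regime estimates \(\sigma \approx 0.99\) and the subcritical (0.5) /
  supercritical (1.5) regimes order correctly around 1.
* density 0.5 makes the ATM-versus-ground-truth comparison rank-meaningful:
  at low density most ordered pairs are zero-weight ties and rank
  correlation is dominated by confound noise on those ties.

Rendering to continuous series places a ±1 boxcar pulse (random sign) at
every active sample and Gaussian noise on the background samples. After
z-scoring, total variance is fixed, so pulse height and background level
cannot be chosen independently: with `noise_sd = NULL` the background level
is solved per ROI so pulse peaks land at `burst_amplitude_z` (default 2.5);
passing a small explicit `noise_sd` instead gives the low-noise regime
(pulse z near \(1/\sqrt{q_r}\) for activity fraction \(q_r\)), where the
binarize→detect round trip is essentially exact. The generator reproduces
the *geometry* of avalanche data — sparse aperiodic bursts on a stationary
background — but not 1/f spectra, oscillations, waveform shape, or
inter-subject variability in graph structure; passing tests therefore
demonstrate the pipeline's correctness and sensitivity, not clinical
performance.

## Numerical choices and degenerate inputs

* DPSS tapers come from the symmetric tridiagonal eigenproblem (unit-norm
  columns, conventional signs) and are cached per (length, NW, K).
* Zero-variance ROI rows abort binarization with the ROI named; zero
  autospectral density aborts ImCoh with ROI and frequency named.
* Zero-variance training features are retained with unit scale rather than
  dropped, keeping the edge space fixed across splits.
* Trailing partial bins at re-binning are dropped, not padded — padding
  would fabricate silence and end avalanches artificially.
* Bin intervals are 0-based and half-open throughout (`[start, end)`);
  ROI indices are 1-based.
* Precision/F1 are defined as 0 when no positive predictions exist.
* SVM fits run on a rank-reduced representation of each split: train and
  test rows are projected onto an orthonormal basis of their joint row span,
  which preserves inner products and pairwise distances — hence linear and
  RBF solutions — exactly, while the quadratic programs see a matrix of
  width `n_subjects` rather than `n_edges`. Linear coefficients are mapped
  back to edge space through the same basis.
* The band-pass in `run_pipeline()` is a zero-phase forward–backward
  Butterworth of order 4 (no source-space filter design is canonical; this
  is documented rather than prescribed).

## Problem sizes used in the test-suite and calibration runs

Simulated calibrations use sizes chosen to make sampling error small
relative to the tested tolerances while staying desk-scale: branching-ratio
calibration on ≥ 500 (typically ~2,500) avalanches from 30,000-bin rasters;
graph recovery on one 300 s, 68-ROI subject; classifier calibration on
30 + 30-subject cohorts at full study conditions; the window-length trend
on a 12 + 12 cohort with lengths {5, 30, 300} s and 10 placements. The
surrogate null uses 200 circular shifts.

## Known limitations

* The window-length analysis requires each window to fit inside one
  recording segment; recordings chopped into segments all shorter than the
  longest requested window are rejected rather than spliced.
* Importance is defined only for linear-kernel splits; an all-RBF grid
  errors by design.
* The simulator's noisy-OR propagation has no inhibition, delays beyond one
  bin, or 1/f background; `select_bin_size()` on such data is nearly flat
  across small bins (see above).
* ImCoh magnitudes depend on taper bandwidth near sharp spectral peaks;
  comparisons should hold `spectral_params()` fixed across subjects, as the
  pipeline does.
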