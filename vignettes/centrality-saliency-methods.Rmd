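---
title: "Methods: time-varying network centrality and visual saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-varying network centrality and visual saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salnet)
```

This vignette is the package's own account of the analysis it implements:
the models and procedures, the parameters that matter, the numerical
choices made where conventions diverge, what the synthetic-data generator
does and does not emulate, and the known limitations.

## Network construction

Each participant's parcellated fMRI data enter as a parcels × time matrix.
Per run, every parcel is z-scored (mean 0, SD 1) before runs are
concatenated; a zero-variance parcel is an error, not silently imputed,
because a flat parcel almost always indicates an upstream extraction
problem. The Pearson correlation matrix of the concatenated series is then
binarized by a *proportional threshold*: the `round(p · N(N−1)/2)` largest
off-diagonal values become edges. Choices behind this operator:

- **Signed thresholding.** The largest *signed* correlations are kept, not
  the largest absolute values. At sparse densities on typical
  functional-connectivity matrices negative correlations never reach the
  retained range, and the signed rule matches common binary-undirected
  practice.
- **Rounding and ties.** Edge count is round-half-up of `p · N(N−1)/2`.
  Ties at the cutoff are broken by ascending (row, column) index, which
  makes the edge set deterministic and nested across densities (the
  network at 5% is always a subgraph of the network at 10%).
- **Disconnection is allowed.** No giant-component enforcement; see the
  eigenvector-centrality convention below.

The default density of 7.5% is not arbitrary: it is selected as the
maximizer of the mean *flow coefficient* over the candidate grid
{2.5, 5, 7.5, 10, 12.5, 15}%, computable per dataset with
`select_density_by_flow()`. The flow coefficient of a node is the fraction
of its neighbor pairs not directly connected to each other — on a binary
undirected graph exactly `1 − local clustering`, with nodes of degree < 2
assigned 0. A density maximizing it yields networks whose nodes mediate
most strongly between their neighbors.

## Centralities

**Eigenvector centrality** is the leading eigenvector of the adjacency
matrix, computed by a full symmetric eigendecomposition rather than power
iteration: the dense solver is deterministic, and at N ≤ a few hundred it
is not a bottleneck. Power iteration survives in the test suite as an
independent oracle. The vector is sign-fixed non-negative and scaled to
unit Euclidean norm. On a disconnected graph the eigenvector of the
*globally* largest eigenvalue is returned; its support concentrates on one
component and all other components get near-zero centrality. Users should
be aware of this when thresholding very sparsely.

**Communities** come from Louvain modularity maximization (via igraph)
at resolution γ = 1. Louvain is greedy and order-dependent, so the
partition is the best of `n_restarts` seeded runs (default 100 for static
networks). Reproducibility is from `(seed, n_restarts)` exactly.

**Participation coefficient** uses the community cross-tabulation of each
node's edges; isolated nodes get PC = 0 by convention (the defining ratio
is 0/0 there). PC is identically 0 under a single-community partition.

## Sliding windows

Time-varying centralities repeat correlate → threshold → centrality inside
a rectangular window of 50 s — 25 s each side of the center — advanced one
sample per step, so the first and last half-window of a scan produce no
output. Window length in samples is `round(50 / TR)`; at TR = 1 s the
half-open convention `[t−25, t+25)` gives 50 samples and `T − 49` windows.
The endpoint convention is a documented choice — either inclusion rule is
defensible; the half-open one keeps window length exactly L at every
center.

Each output column is *by construction* identical to the static metric
computed on that window's samples, and the test suite asserts this
equality exactly rather than approximately. Per-window Louvain partitions
use seeds derived deterministically from `(seed, window index)` and 10
restarts (against 100 for static networks): windows number in the
hundreds, the per-window networks are small, and in testing the best-of-10
modularity was already stable; the cost of 100 restarts per window would
be paid hundreds of times over. Windows containing a zero-variance parcel
are filled with NA and warned about, not fatal — a single flat stretch
should not abort a participant.

No tapering is applied (rectangular window), matching the plain sliding
window the centrality literature uses here.

## Visual saliency

The saliency model is the classic bottom-up architecture: per frame,

1. channels — intensity I = (R+G+B)/3; color opponency RG and BY from the
   broadly tuned opponents R = r − (g+b)/2 etc., negatives clamped, all
   color suppressed where I < max(I)/10 (low-luminance rule); four Gabor
   orientation energies (0°, 45°, 90°, 135°; wavelength 7 px, aspect 1,
   two quadrature phases) on the intensity pyramid;
2. dyadic Gaussian pyramids, levels 0–8, built with a separable 5-tap
   binomial kernel and factor-2 decimation (ceiling dimensions at odd
   sizes);
3. center–surround contrast `|center − upsampled surround|` for center
   levels 2–4 and surround offsets 3–4 — 6 intensity, 12 color and 24
   orientation maps, all resampled bilinearly to level 4 (1/16 of input;
   64 × 45 for 1024 × 720 content);
4. max-norm normalization: each map is rescaled to [0, 1] and multiplied
   by (M − m̄)², M the global maximum and m̄ the mean of the other strict
   3 × 3 interior local maxima — maps with one dominant peak keep their
   weight, maps with many comparable peaks are suppressed;
5. normalized maps are summed into per-channel conspicuity maps,
   normalized again, and averaged across the three channels.

The closed-form (M − m̄)² operator was chosen over the iterative
difference-of-Gaussians variant for determinism and speed; both are in use
in the literature and they rank typical frames similarly, but absolute map
values differ between variants, so downstream consumers should rely on the
signal's *temporal structure*, which the per-TR averaging and correlation
analysis do.

Two numerical guards matter. Kernels cropped to fit tiny pyramid levels
must have their defining property restored — unit sum for the smoothing
kernel, zero DC for Gabor kernels — or featureless images acquire spurious
contrast. And maps that are constant to within numerical noise (< 1e−9
range) pass through normalization unrescaled, since rescaling FFT residue
into [0, 1] manufactures structure from nothing.

The mean saliency signal averages each TR bin's F = fps · TR maps over all
pixels and frames (F must be integral; a trailing partial bin is dropped),
and is low-pass filtered at 0.1 Hz with an order-5 Butterworth applied
forward and backward (zero phase). R's `signal::filtfilt` does not pad, so
the package adds odd (point-symmetric) reflective padding of 3 · 6 · order
samples at each end before filtering; DC gain is 1, so constant signals
pass unchanged.

## Group statistics

Per-parcel correlations between a centrality time course and the saliency
signal are aligned by window-center sample index (the signal is trimmed to
the window centers) with an optional integer-TR lag, default 0 and no
hemodynamic convolution. Correlations are Fisher-z transformed and tested
across participants — one-sample against zero, or paired between two
conditions. Two-tailed p values are Bonferroni-corrected over the number
of parcels and reported as signed standard-normal equivalents
`Z = sign(t) · Φ⁻¹(1 − p/2)`. The significance cutoff is *computed* from
the configured FWE level and test count (Z ≈ 4.19 at FWE 0.01 over 360
parcels) rather than hard-coded, so it adapts to other parcellations.

For comparing two independent spatial map correlations the package
provides Fisher's test `Z = (atanh r₁ − atanh r₂)/√(2/(n−3))`. Note that
for dependent correlations sharing a map this overstates Z; the dependent
variant needs the cross-map correlation, which callers rarely have, and is
deliberately not guessed at.

The group-average correlation map averages on the Fisher-z scale and
back-transforms (`tanh(mean(atanh r))`), which is invariant to participant
order and less biased than averaging r directly.

## The synthetic-data generator

`cohort_spec()` defines a block factor model: parcel i in community c at
time t is

x_i(t) = a · g_c(t) + b(t) · h(t) + ε_i(t),

with community factors g_c, a global factor h and i.i.d. noise ε of SD σ.
The loadings map to target correlations as v = σ²/(1 − r_within),
b² = r_between · v, a² = (r_within − r_between) · v, so the population
correlation is r_within inside blocks and r_between across them — the test
suite verifies recovery at T = 2000 within 3/√T. Coupled parcels have
their global-factor (cross-community) loading scaled by
`max(0, 1 + gain · z(t))` with z the z-scored driver; the floor prevents
accidental sign flips, while a negative gain inverts the coupling by
intent. At gain 0 the code path is identical to the stationary generator,
so gain-zero equivalence is exact, not approximate.

The reference study conditions (`planted_cohort_spec()`) are 20
participants, 60 parcels, T = 900 at TR = 1 s, coupling gain 1.5 and a
0.01 Hz sinusoidal driver — slow enough for a 50 s window to track. The
coupled set is an entire small community (6 parcels; sizes 6/18/18/18)
with r_within = 0.5 and r_between = 0.25. These defaults were calibrated
by Monte Carlo before the validation thresholds were frozen, and the
calibration taught us two things about the *mechanism*, not just the
generator. First, eigenvector centrality has unit norm, so any
driver-locked increase in coupled parcels' centrality is compensated by a
decrease elsewhere — with enough participants that compensation becomes
statistically visible in truly uncoupled parcels. Second, when coupled
parcels share a community with uncoupled ones, their community-mates'
centrality rides up with them (a real network effect, not a bug), which
would be counted as false positives against parcel-level ground truth.
Making the coupled set a complete small community and keeping the baseline
cross-community correlation near the threshold cutoff yields a clean
planted effect: group-mean coupled r ≈ 0.5, uncoupled parcels at chance,
stable across seeds.

The movie generator produces 8-bit RGB frames with isotropic Gaussian
blobs (truncated at 3σ) on a uniform background, with per-frame
ground-truth masks. Frames are quantized to 8 bits in memory so written
PNGs round-trip bit-exactly.

What the generator does *not* emulate: hemodynamics (no HRF), realistic
fMRI noise spectra (white noise only), vertex-level structure below the
parcel, scanner drift or motion artifacts, and natural image statistics.
Passing tests therefore show the pipeline recovers the planted
correlational structure it is designed to detect — they do not certify
performance on real data, where effect sizes, autocorrelation and
confounds differ.

## Problem sizes and runtime

Validation uses 60-parcel cohorts (the package supports any N), windows
over T = 900 samples, 256 × 256 px frames for most saliency tests with
single 1024 × 720 frames for the geometry contract, 200 repetitions for
the family-wise-error calibration, and 50 random graphs for solver-oracle
agreement. The full test suite runs in about a minute on one CPU.

## Known limitations

- Eigenvector centrality on very sparse, fragmented networks concentrates
  on the largest-eigenvalue component; comparisons across windows with
  different fragmentation mix this in.
- The test count in the FWE cutoff is the parcel count; temporal
  autocorrelation of centrality time courses is not corrected for in the
  per-participant correlations (no effective-degrees-of-freedom
  adjustment).
- The saliency model has no motion/flicker channel, so dynamic salience
  in real movies is under-represented relative to what a motion-sensitive
  model would produce.
- I/O is TSV/JSON/PNG only; neuroimaging container formats are out of
  scope for the core package.
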