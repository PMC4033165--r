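---
title: "Decoding bistable perception from BOLD time series: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding bistable perception from BOLD time series: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtpercept)
```

## The problem

When a constant ambiguous stimulus is viewed — here, an outline figure
moving behind a narrow slit — conscious perception alternates spontaneously
between two mutually exclusive interpretations: vertically jumping *line*
segments, or a coherent, horizontally moving *object*. The perceptual state
is not visible in the stimulus; it lives entirely in the observer's brain.
`rtpercept` implements a complete pipeline for tracking that state, volume
by volume, from fMRI BOLD activity: a synthetic-session generator with
known ground truth, offline decoding with leave-one-run-out
cross-validation, a simulated causal real-time loop, block-preserving
permutation statistics, and cross-subject weight-map transfer.

## The generative model

`simulate_session()` builds sessions from four ingredients.

**Percept timelines.** Dwell times (how long one percept lasts) follow a
gamma distribution, the standard description for bistable alternation.
Two presets reflect the two experimental regimes the package emulates:
offline (shape 2.00, scale 7.51 s, TR 2.5 s) and online (shape 5.29,
scale 4.26 s, TR 2.0 s). Draws below `min_duration` (two TRs by default,
so every interval spans at least two volumes and shifted labels remain
well defined) are rejected and redrawn; the final interval is truncated at
the 420 s run length. A fair coin picks the initial state. The generator
fits one dwell distribution shared by both states, because the empirical
dwell histogram it emulates pools both percepts.

**Haemodynamics.** Neural state changes reach the BOLD signal through the
canonical double-gamma impulse response: a positive lobe peaking at 5 s, an
undershoot peaking at 15 s at one sixth the amplitude, 32 s support. The
5 s peak is deliberately consistent with the fixed 5 s forward shift used
to align percept reports with volumes. The kernel is normalised to unit
integral so a sustained percept produces a plateau of exactly 1, which
makes effect sizes in percent signal change exact plateau amplitudes.

**Voxel populations.** The simulated brain is a desk-scale grid (default
20×20×10 ≈ 4000 voxels standing in for a 64×64×32 acquisition) with an
antagonistic responsive network, emulating the empirical pattern of
object-percept-related activity: `object_positive` voxels (ventral-stream
like) gain signal during object percepts, `object_negative` voxels
(early-visual like) lose it, each ±`effect`% around a baseline of 100 (so
percent signal change equals absolute deviation). A small set of "vessel"
voxels oscillates at 12% amplitude — above the 10% exclusion threshold by
construction, so the vascular screening rule is testable.

**Noise.** Additive AR(1) noise (stationary SD `sigma`, lag-one
correlation 0.3) plus a slow sinusoidal drift (amplitude 1% signal change,
period 128 s, random phase per voxel and run). Defaults were chosen once as
plausible for 3 T EPI at this scale. The generator does *not* simulate
motion, cardiac/respiratory physiology, spatial noise correlations, or
report latency; passing tests therefore demonstrate correctness of the
algorithms under a idealised but non-trivial noise model, not performance
on real scanner data.

## Preprocessing

* **Zero-centring** — offline, each voxel's temporal mean is removed per
  run; online, the baselines stored from the training runs are subtracted
  from incoming volumes without recomputation.
* **Band-pass filtering** — Butterworth 1/128–1/16 Hz. "Order 4" is the
  overall order of the band-pass (an order-2 prototype per edge). Offline
  filtering is zero-phase (forward–backward, so the squared magnitude
  response and no phase shift); the online loop filters causally, forward
  only, because a real-time system cannot see the future. Tests verify the
  filter against FFT amplitude oracles and against the reference
  implementation in the `signal` package rather than against coefficient
  values.
* **Vascular exclusion** — a voxel is excluded iff its maximal deviation
  from its temporal mean exceeds 10% of that mean, with a strict
  inequality (a voxel at exactly 10% is retained); non-positive baselines
  exclude the voxel with a warning.
* **Label shifting** — the volume acquired over `[kT, (k+1)T)` receives
  the state occupying the majority of `[kT−d, (k+1)T−d)` with `d = 5` s.
  A continuous window-majority rule (not integer rounding) keeps TR 2.0
  well defined; ties go to the state occupying the earlier part of the
  window; volumes whose shifted window precedes the run start are
  undefined and excluded from both training and accuracy denominators.
* **Spatial smoothing** — isotropic Gaussian, σ = FWHM/(2√(2 ln 2)) in
  voxel units, nearest-edge replication. The synthetic pipeline defaults
  to no smoothing: informative voxels are placed at random, so smoothing
  would blur signal into uninformative neighbours, unlike real data where
  informative voxels cluster spatially.

## Feature selection and decoding

Voxels are scored by a GLM contrast: per-state boxcars convolved with the
HRF plus an intercept, ordinary least squares per voxel, and the F
statistic for `β_object − β_line = 0` with (1, T−3) degrees of freedom —
identical to the squared contrast t, and, for two conditions, to a one-way
ANOVA (`class_f_scores()` provides the equivalent sample-labelled form
used where no timeline exists, e.g. under permuted labels). The `k`
smallest p-values are retained (offline protocol default 5000; online
first pass 10000; cross-subject maps 30000), ties broken by larger F then
lower index.

The classifier is a soft-margin linear SVM on centred signal-change
features, with no further standardisation. Predictions follow the sign
rule on `w·x + b`; an exact zero maps to OBJECT (arbitrary but fixed).
Offline cross-validation is leave-one-run-out — feature selection, low-pass
cutoff optimisation (candidates 1/27, 1/18, 1/12, 1/8 Hz; inner
leave-one-run-out on the training runs; ties to the lowest cutoff) and
training all happen strictly inside the training fold.

## The simulated real-time loop

Runs 1–2 train the initial classifier: stored baselines, causal filtering,
top-10000 univariate selection, a first SVM pass, multivariate refinement
keeping voxels with `|w| > 0.1·max|w|` (strict, absolute weights — the
sign of an SVM weight is hard to interpret), and retraining on the frozen
refined set. From run 3 on, each volume is baseline-subtracted, advanced
through the causal filter by one sample (direct-form II transposed state,
reset at run boundaries), and classified; a switch event is emitted exactly
when the prediction changes (the first prediction of run 3 emits none).
After every completed run the classifier is retrained on all data so far.

Two design choices here deserve explanation:

* **Label alignment under causal filtering.** A causal band-pass delays
  what it passes. The relevant lag for a percept alternation is the
  *phase* delay at the alternation fundamental (≈ 1/(2·mean dwell),
  estimated from the training runs' reports and clamped into the
  passband), which for the default filter sits near band centre and is
  small; the *group* delay (envelope lag, 6–9 s here) is the wrong
  quantity and mis-aligns labels so badly that features become
  uninformative. Online training and scoring therefore shift labels by
  `hrf_delay + filter_phase_delay`; the HRF-only-aligned accuracy is also
  reported.
* **Cost selection.** With two training runs, the sample count and the
  feature dimension are of the same order, and causally filtered
  switch-lag samples are *coherently* mislabelled; at a fixed C = 1 the
  hinge loss buys those samples off with noise directions and the learned
  weights decorrelate from the planted signal. Initial training therefore
  selects C from a log grid by two-fold cross-run validation (train run 1,
  validate run 2, and vice versa, feature selection inside the fold) — the
  same in-training-set optimisation pattern the offline pipeline uses for
  its low-pass cutoff. The offline decoder keeps the fixed default C = 1,
  which its larger training sets and zero-phase features tolerate.

## Permutation statistics

Volume-wise label shuffles are anti-conservative for autocorrelated time
series, so all nulls permute *blocks* of consecutively equal labels,
preserving the dwell-time structure; blocks never straddle run boundaries.
`guessing_level_ci()` reruns the full cross-validated pipeline (feature
selection inside every fold, class-F scoring for both the observed and the
permuted runs so the comparison is like-for-like) per permutation — 500 in
the full protocol — and reports the null mean and percentile interval; an
observed accuracy is reliable only above the upper bound. A fast
approximate mode (`refit_features = FALSE`) freezes the feature set across
permutations.

`weight_significance()` retrains one classifier per permuted label vector
and computes `p_w(k)` as the fraction of permutations whose absolute
weight at voxel k reaches the observed one (ties count as exceeding —
conservative). Weight vectors are normalised to unit length first: a
maximum-margin weight norm scales *inversely* with separability, so raw
magnitudes of an informative fit and of permuted fits are not on a common
scale; the normalised weight measures a voxel's relative contribution to
the separating direction. Pure-null calibration (uniform `p_w`) is
verified in the test suite. `conjunction_mask()` intersects two maps at a
strict `p_w < 0.1`.

## Cross-subject transfer

Sessions are reduced to one sample per sustained-percept interval — the
mean of the three volumes centred on the interval's middle defined volume
(earlier middle for even lengths; shorter intervals contribute what they
have) — both to cut data volume and because switch-adjacent volumes are
unreliable. Per subject, a top-30000 selection and SVM yield a weight map
embedded in the common grid, weighted by that subject's own
leave-one-run-out accuracy `p̂` (computed on the reduced samples) in the
combination

w̄ₖ = (1/n) Σᵢ 2(p̂ᵢ − ½) wᵢₖ,

applied verbatim — per-subject weight vectors are not re-normalised, and a
chance-level subject contributes nothing while a below-chance subject
flips sign. Leave-one-subject-out validation combines the training
subjects' maps, keeps the 30000 highest-|w̄| voxels, trains a fresh
classifier on the pooled training-subject samples, and scores the held-out
subject, which is never touched during map building or selection. All
simulated subjects share one grid, standing in for template-space
normalisation.

## Evaluation utilities

`switch_local_accuracy()` splits defined volumes into a near-switch set
(the switch volume ± 1, a symmetric reading of "three volumes around a
switch") and its complement. `fit_gamma()` offers maximum likelihood (the
method used for recovery checks, since histogram binning choices are
arbitrary) and histogram least squares with R² (3 s bins by default).
`gamma_mode()` is `(shape−1)·scale` for shape > 1, else 0, cross-checked
against a dense-grid argmax. `signed_tmap()` reports pooled-variance
two-sample t values (object minus line) on reduced samples with honest
degrees of freedom, and `critical_t()` the two-sided threshold.

## Problem sizes used by the tests

The test-suite and end-to-end checks run at desk scale, chosen once:
signal-recovery sessions use a 12×12×6 grid with 120 informative voxels,
8 runs of 420 s, effect 1.5% and noise SD 0.3%, with retention sizes
scaled in rough proportion to the protocol's fraction of the voxel
population (300 of 864, vs. 5000–10000 of a whole head); the permutation
null-calibration uses a zero-effect 8×8×4 session with 100 permutations;
transfer uses six subjects on a 10×10×5 grid sharing one informative
layout. Exact-count checks of the 5000/10000 retention sizes run on an
11520-voxel scored population.

## Known limitations

* The causal band-pass imposes a hard ceiling on online tracking: even a
  perfect sign readout of the causally filtered ideal response attains
  only ≈ 0.84 overall and ≈ 0.90 away-from-switch accuracy under the
  online dwell statistics, because group-delay dispersion smears percept
  transitions beyond the three-volume switch window. The simulated loop
  operates essentially at this ceiling; materially higher online accuracy
  would require a different causal filter or temporal-embedding readout,
  both out of scope.
* Synthetic noise is temporally but not spatially structured; selection
  and smoothing behave more favourably here than on real data.
* The generator models no report latency by default (`jitter_reports()`
  adds it on demand) and shares one dwell distribution across states.
* `p̂` for the group combination uses reduced-sample leave-one-run-out
  accuracy; with very few intervals per run it is a coarse estimate.
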