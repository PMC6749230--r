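---
title: "Identifying people from smart-insole gait data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from smart-insole gait data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(soleID)
```

## The problem

A smart insole instruments each foot with 8 plantar-pressure sensors
(quantized to three levels: 0 = foot off the ground, 1 and 2 = increasing
contact pressure) and a triaxial accelerometer, all sampled synchronously at
100 Hz. Because gait patterns are individual, a short stretch of ordinary
walking recorded by such an insole carries enough information to identify
who is wearing it. soleID implements the full identification pipeline:
segmentation of continuous walking into gait cycles, length normalization,
per-modality discriminant feature extraction with null-space LDA, supervised
Laplacian-score fusion of the two modalities, and 1-nearest-neighbour
classification, evaluated with a repeated random-split protocol.

The regime is deliberately *small-sample*: identification must work from
as few as three training samples per person, while each sample is a
high-dimensional vector (1008 values for pressure, 378 for acceleration per
step). Classical LDA is ill-posed here because the within-class scatter
matrix is singular; the null-space variant turns that singularity into the
main asset.

## Preprocessing

**Segmentation.** The swing phase of a foot is the interval during which
all 8 of its pressure sensors read zero. The first frame of each maximal
all-zero run is the *swing-phase onset*, the one unambiguous event in the
quantized signal, and a gait cycle is the half-open frame interval from one
onset of the reference foot to the next. We use the left foot by default
(the choice is configurable and immaterial to the math: both feet's 16
pressure and 6 acceleration channels travel together in every segment).
Partial leading/trailing cycles are discarded, and segments shorter than
`minCycleFrames = 10` frames (0.1 s — far below any plausible gait cycle)
are dropped as sensor glitches.

**Length normalization.** Walking speed varies within a person and would
inflate within-class variance, so each cycle is resampled to a fixed length
`l = 63` frames. Each channel is interpolated linearly on the uniform grid
mapping `[0, T-1]` onto `[0, 62]`. Linear interpolation is chosen because
it is monotone, preserves constants exactly, and introduces no ringing on
the piecewise-constant pressure signals; the resampled pressure values are
real numbers and are *not* re-quantized — downstream algebra has no use for
the 3-level coding.

**Vectorization.** The `63 x 16` and `63 x 6` matrices are flattened
lexicographically (row-major, time index varying slowest) into vectors of
length 1008 and 378.

**Regularization.** Because every sample's swing stretch is exactly zero in
the same positions, the sample covariance would be rank-deficient in a
structured way that destabilizes eigendecomposition. Each step vector
therefore receives independent additive noise drawn uniformly from
[0, 0.1) — small against the 0/1/2 pressure coding and the order-1
acceleration amplitudes. The noise is applied once per step, to both
modalities, to training and test samples alike, at grouping time, under an
experiment-level seed. Whether to draw noise per step or per grouped sample
is an open choice; we draw per step so a `k`-step sample is exactly the
concatenation of its regularized steps.

**Step grouping.** A classifier sample is `k` consecutive steps
(non-overlapping windows, `k = 1..3` in the evaluation sweep); `n` steps
yield `floor(n / k)` samples and the leftovers are discarded.
Non-overlapping windows keep samples statistically independent, and the
resulting sample counts shrink as `sum_s floor(n_s / k)`.

## Null-space LDA

With `N` training samples in `C` classes and dimension `n`, let `S_W` and
`S_B` be the unnormalized within- and between-class scatter matrices
(`S_B` weighted by the class sizes `N_i`). In the small-sample regime
(`n > N - C`) the null space of `S_W` intersected with the span of the data
is non-trivial, and projecting onto it collapses every training class to a
single point — within-class variance is exactly zero. NLDA chooses, inside
that null space, the directions maximizing `W' S_B W`, yielding at most
`C - 1` features ordered by between-class eigenvalue.

The fit never forms the `n x n` scatters. Three stages, all inside the span
of the data:

1. SVD of the globally centered data gives an orthonormal basis `U` of the
   significant total-scatter eigendirections (rank at most `N - 1`).
2. Within `span(U)`, the within-class scatter is a small `r x r` matrix;
   its eigenvectors with eigenvalues below the threshold form the
   null-space basis `Q`.
3. The between-class scatter restricted to `span(UQ)` is eigendecomposed;
   its top `C - 1` eigenvectors `V` give `W = U Q V`, which has exactly
   orthonormal columns.

**Numerical choices.** Eigenvalue thresholds are relative:
`tol = 1e-10` times the leading *total-scatter* eigenvalue, applied at
every stage, so "zero" means zero on the scale of the data. Anchoring the
threshold to the total scatter (rather than per-matrix maxima) keeps the
null-space test meaningful when `S_W` is itself tiny or exactly zero (for
example with one sample per class). All eigendecompositions use the
symmetric solver on explicitly symmetrized matrices, making fits
bit-for-bit reproducible. Ties among equal between-class eigenvalues keep
the solver's stable order; degenerate spectra are possible in principle but
do not arise under the study conditions.

**No centering in the transform.** The projection is applied as `y = W'x`
without subtracting the global mean. Centering would shift all features by
a constant vector; the 1-NN classifier uses only pairwise Euclidean
distances, which are translation-invariant, so the choice is immaterial to
every reported number — and keeping the raw linear map makes the transform
a pure function of `W`.

A fit fails loudly when the data are not in the small-sample regime (no
usable null space) or when more components are requested than the
between-class rank supports.

## Multi-modal fusion by supervised Laplacian score

NLDA is fitted separately per modality because pressure (3-level, spatial
contact pattern) and acceleration (continuous, dynamic) carry different
information. The two `C - 1`-dimensional feature vectors are concatenated,
pressure first, into a candidate vector of length `p = 2(C - 1)`.
Eigenvalues are not comparable across modalities, so features are re-ranked
by a supervised Laplacian score: build a graph on the `N` training samples
with an edge between every same-class pair, weighted
`exp(-||y_i - y_j||^2 / m)` with bandwidth `m = 2` and no self-loops
(self-loops add equal mass to the degree and weight terms; fixing the
convention makes tests exact). With degree matrix `D`, Laplacian
`L = D - W` and the `D`-weighted centering
`f~ = f - (f'D1 / 1'D1) 1`, feature `r` scores
`LS_r = (f~' L f~) / (f~' D f~)`; a constant feature scores 0 by
convention. The score is invariant to shifting a feature by a constant.

**Selection direction.** We select features with *larger* scores, the
direction this pipeline uses throughout. Note this inverts the classical
unsupervised Laplacian-score semantics, where smaller is better
(locality-preserving); on the supervised same-class graph a large quadratic
form `f~' L f~` relative to the global variance term flags features whose
within-class geometry is informative. Both directions are exposed
(`direction = "larger"` / `"smaller"`); under the standard synthetic
conditions either direction identifies perfectly, so the package default
simply follows the pipeline's convention. Ties break toward the lower
candidate index, deterministically.

The multi-modal vector keeps the best `d` candidates; identification rates
saturate by around 20 dimensions, so the default operating point is
`d = min(20, p)`. The graph, scores and selection are recomputed from each
repeat's training samples only, and the training-derived selection is
applied unchanged to test candidates.

## Evaluation protocol

Per repeat: group steps into `k`-step samples (fresh regularization noise),
draw a pool of `nTotal = 700` samples (or all samples when the cohort
yields fewer, as the desk-scale simulations do), draw
`nTrainPerSubject = 3` training samples per subject uniformly from the
pool, fit everything on those training samples, and classify the rest with
1-NN on Euclidean distance (distance ties toward the lower training index).
The pool draw is uniform, not stratified by subject; per-subject counts are
recorded and the protocol errors if any subject cannot supply 3 training
plus 1 test sample. Both the pool and the split are re-drawn every repeat
from per-repeat seeds spawned by one master seed, and results are averaged
over `nRepeats = 25` by default. Single-modal baselines use the
per-modality NLDA features directly, in between-class-eigenvalue order
(capped at `C - 1`), without Laplacian re-ranking. A label-shuffling switch
provides a chance-level control (expected accuracy `1/C`). No information
flows from held-out samples into any fitted artifact — a property the test
suite asserts by scrambling held-out samples and checking the fit is
unchanged.

## The synthetic cohort generator

No public dataset accompanies this problem setting, so the package ships a
simulator that generates dual-foot recordings with the statistical
structure the method relies on — it is a test harness, not a claim about
gait physiology. Each subject is a perturbation of a shared population
prototype, with `separation` scaling all between-subject differences:

* **Pressure:** each sensor activates over a subject-specific window of the
  stance phase (heel sensors from stance onset, forefoot sensors through
  push-off) at a peak level of 1 or 2; window edges shift by up to ±0.08 of
  the stance per unit separation, and peak levels occasionally flip. One
  heel sensor always covers the start of stance and one forefoot sensor the
  end, so no stance frame is all-zero and swing runs stay maximal —
  guaranteeing segmentability by construction.
* **Acceleration:** a 3-harmonic sinusoid per channel (amplitudes ~1, 0.5,
  0.25 in arbitrary sensor units, matching the unit-agnostic I/O
  convention) with subject-specific amplitude and phase perturbations, plus
  Gaussian noise (`accelNoiseSd = 0.3`).
* **Timing:** cycles last ~1.0–1.3 s at 100 Hz (subject mean 115 ± up to
  15 frames), 60/40 stance/swing split, the right foot offset by half a
  cycle; within subject, cycle length varies with CV 0.05 and activation
  windows jitter per step (sd 0.02 of stance). A trailing partial swing is
  appended so the last complete cycle ends at a detectable onset, and the
  generator returns exact `[start, end)` boundaries under the same
  swing-onset convention the segmenter uses, so oracle comparisons are
  exact.

With `separation = 0` all subjects are identical; template distances grow
monotonically with `separation` (the underlying random deviates are drawn
independently of it), which the tests use to verify that identification
difficulty is controllable.

**What the simulator does not emulate:** sensor dropout and quantization
artifacts, gait drift across days, footwear and surface effects, speed–
pattern correlations, pathological gaits, and any realistic accelerometer
spectrum beyond three harmonics. Passing tests on this cohort therefore
demonstrate correctness of the pipeline and its protocol — not field
accuracy on real populations.

## Problem sizes used in the shipped evaluation

The standard operating point throughout the tests and the acceptance
script is 14 subjects × 40 steps each (560 one-step samples, 42 training /
518 test), 5 repeats, `k = 1..3`. At these sizes the full sweep runs in
well under a minute on a laptop core while keeping ≥ 150 test samples at
`k = 3`. Under these conditions the multi-modal identification rate is at
ceiling (100%), single-modal baselines likewise, and the label-shuffled
control sits at `1/14 ≈ 7.1%`:

```{r, eval = FALSE}
sim <- simulateCohort(cohortSpec(seed = 1))
r <- runExperiment(sim$sessions, experimentConfig(nRepeats = 5, seed = 7))
r
#> ExperimentResult: 5 repeats, k in {1}
#>   acceleration  k=1: 1.000 +/- 0.000
#>   multimodal    k=1: 1.000 +/- 0.000
#>   pressure      k=1: 1.000 +/- 0.000
```

A ceiling result is expected here: the simulated between-subject
separation at its moderate default is large relative to the within-subject
noise, and NLDA collapses each class to a point. The scientifically
interesting regressions are therefore the *relative* properties — fusion
never losing to either single modality, accuracy degrading to chance as
`separation` approaches 0, and `k = 3` samples never identifying worse than
`k = 1` — all of which are asserted in the test suite.

## Known limitations

* The pipeline assumes clean swing phases; a subject who never fully
  unloads one foot (shuffling gait) produces no segments.
* NLDA's collapse of classes to points can overfit tiny training sets when
  within-class variation at test time leaves the training null space; the
  regularization noise mitigates but does not remove this.
* The 3-per-subject training rule is part of the protocol contract;
  cohorts where some subject cannot supply 4 samples at the chosen `k`
  error out rather than silently rebalancing.
* Feature selection assumes both modalities were fitted with the same
  number of components (`C - 1` each).
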