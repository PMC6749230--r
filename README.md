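# soleID

Identify people from the way they walk, using dual-foot smart-insole
recordings: 16 plantar-pressure channels (8 per foot, quantized to
0/1/2) and 6 acceleration channels (triaxial per foot), sampled
synchronously at 100 Hz.

soleID is aimed at researchers in gait biometrics and wearable sensing who
need a complete, reproducible identification pipeline for this kind of
multi-modal time series — and at anyone who needs its building blocks:
swing-phase gait-cycle segmentation, null-space discriminant analysis for
the small-sample regime, or supervised Laplacian-score feature fusion.

## The method

1. **Segmentation.** A gait cycle runs from one *swing-phase onset* of the
   reference foot (first frame where all 8 of its pressure sensors read 0)
   to the next. Each cycle is resampled to a fixed length *l* = 63 frames
   by linear interpolation, flattened lexicographically into per-step
   vectors (1008 pressure values, 378 acceleration values), and
   regularized with additive Uniform[0, 0.1) noise to restore numerical
   rank. A classifier sample concatenates *k* consecutive steps.

2. **Null-space LDA (per modality).** With within/between-class scatters

       S_W = Σᵢ Σ_{x∈cᵢ} (x − μᵢ)(x − μᵢ)ᵀ,
       S_B = Σᵢ Nᵢ (μᵢ − μ)(μᵢ − μ)ᵀ,

   the projection solves W_opt = argmax_{WᵀS_W W = 0} WᵀS_B W: inside the
   null space of S_W — which collapses every class to a point — it keeps
   the C − 1 directions of maximal between-class scatter. Features are
   y = Wᵀx.

3. **Fusion.** Pressure and acceleration features are concatenated into a
   candidate vector of length 2(C − 1) and re-ranked by a supervised
   Laplacian score on the same-class sample graph with Gaussian weights
   exp(−‖yᵢ − yⱼ‖²/m), m = 2:

       LS_r = (f̃ᵣᵀ L f̃ᵣ) / (f̃ᵣᵀ D f̃ᵣ),   f̃ᵣ = fᵣ − (fᵣᵀD1 / 1ᵀD1)·1.

   The *d* best-scoring features form the multi-modal vector (default
   d = min(20, 2(C − 1))).

4. **Identification.** A 1-nearest-neighbour rule under Euclidean
   distance, evaluated by a repeated random-split protocol: per repeat,
   draw a pool of 700 samples, use 3 samples per subject for training,
   classify the rest, and average over 25 repeats.

Because no public dataset exists for this sensor layout, the package
includes a synthetic cohort simulator (`cohortSpec()`, `simulateCohort()`)
that generates labeled recordings with subject-specific stance-pressure
patterns and acceleration waveforms, plus exact ground-truth cycle
boundaries for oracle testing.

## Worked example

```r
library(soleID)

# a 14-subject cohort, 40 steps each, moderate between-subject separation
sim <- simulateCohort(cohortSpec(seed = 1))

# repeated random-split evaluation: 3 training samples/subject, 5 repeats
cfg <- experimentConfig(nRepeats = 5, seed = 7)
runExperiment(sim$sessions, cfg)
#> ExperimentResult: 5 repeats, k in {1}
#>   acceleration  k=1: 1.000 +/- 0.000
#>   multimodal    k=1: 1.000 +/- 0.000
#>   pressure      k=1: 1.000 +/- 0.000
```

Each line is the mean ± sd identification rate (fraction of the 518
held-out gait samples whose predicted subject is correct) for one feature
set: the two single-modality NLDA baselines and the fused multi-modal
features. At this separation the cohort is fully identifiable; shrink
`separation` in `cohortSpec()` toward 0 and accuracy falls to the 1/14
chance level (`shuffleLabels = TRUE` gives the same control on any cohort).

Deploying on new recordings:

```r
idf <- fitIdentifier(sim$sessions, experimentConfig(seed = 2))
fresh <- synthSession(sim$templates[[3]], nSteps = 6, seed = 99)
identifySubject(idf, fresh$session, seed = 5)$label
#> [1] "S03"
```

A thin command-line front end (`inst/cli/soleid.R`) exposes `simulate`,
`preprocess`, `evaluate`, `train` and `identify` subcommands over YAML
configs; every run writes a manifest sufficient to reproduce it exactly.

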