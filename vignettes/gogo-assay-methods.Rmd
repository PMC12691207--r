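---
title: "Models and methods behind the Go/Go assay pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the Go/Go assay pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gogoassay)
```

## The assay

In the Go-to/Go-away ("Go/Go") paradigm a single zebrafish swims freely in a
250 × 130 mm tank with an LCD screen pressed against one short wall. Two
complex sounds act as conditioned stimuli: a noise-embedded constant-frequency
tone train (NCF) predicts a rewarding video (a swimming shoal of conspecifics)
and a downward frequency-modulated sweep train (DFM) predicts an aversive one
(a bullfrog). Both cues demand movement — toward the screen after NCF, away
after DFM — so the conditioned response is read from continuous swim
trajectories rather than from a binary choice. The analysis window is the ~3 s
silent gap between sound offset and video onset: behavior there reflects the
animal's prediction, not a reaction to the video itself.

A session comprises eighteen runs in three six-run blocks: Block 1 presents
one cue throughout, Block 2 the other (which comes first is randomized per
fish), and Block 3 interleaves three runs of each cue in randomized order.
Each run is a 10 s pre-cue baseline, 6 s of sound, the 3 s gap, the video,
and a randomized 100–200 s inter-trial interval; 6 min free-swim baselines
bracket the session. Tracking is 10 fps head/tail/heading, analyzed in a
canonical frame where `x` is distance from the screen plane (0 at the
screen).

This package implements the full analysis chain — stimulus synthesis,
timeline construction, tracking I/O, kinematic feature extraction, positional
density and decision-zone analysis, and the inference layer — together with
an agent-based trajectory simulator that stands in for the (unreleased) real
tracking data as the pipeline's testbed.

## Stimulus synthesis

`synthesize_ncf()` builds five 1 s pulses, each the sum of three
equal-amplitude harmonics of a 500 Hz fundamental plus a gaussian noise bed
spectrally confined to 500–1500 Hz and gated inside the pulse, separated by
250 ms silences for a 6 s total. `synthesize_dfm()` builds six 500 ms sweeps
whose fundamental glides linearly from 500 to 50 Hz with three phase-coherent
harmonics (instantaneous frequency of harmonic *k* is
`k (f0 + (f1 − f0) t/T)`, so the train spans 50–1500 Hz), each followed by a
500 ms silence. Choices the published description leaves open, fixed here
once:

* **Silence partition.** Only the pulse counts, pulse durations and the 6 s
  totals are printed; the uniform partitions consistent with them are 4 × 250 ms
  silences (NCF) and 6 × 500 ms silences (DFM).
* **Sweep law.** A linear-in-frequency glide 500 → 50 Hz reproduces the
  printed 50–1500 Hz span across three harmonics. A nominal "5 Hz per ms"
  sweep rate is inconsistent with that span (it would cover 2500 Hz in
  500 ms, matching neither the fundamental's 0.9 Hz/ms nor the third
  harmonic's 2.7 Hz/ms); the linear law is used and the rate is derivable
  from `instantaneous_frequency()` rather than being a free parameter.
* **Noise level.** The level of the noise bed relative to the tonal component
  is unspecified; default 0.25 (linear RMS ratio), configurable.
* **Plumbing.** 44.1 kHz sampling, 5 ms raised-cosine ramps per pulse,
  overall RMS scaled to `target_rms` over the full 6 s. `match_rms()` scales
  the second cue to the first cue's RMS exactly, mirroring the energy
  matching of the two cues.

`segment_envelope()` (smoothed rectified envelope, −40 dB threshold, gap
merging) and `spectral_peaks()`/`spectrogram()` are the verification tools:
they recover pulse counts, durations and harmonic structure from the
synthesized audio, which is what the acceptance checks assert.

## The trajectory simulator

No movement model is published, so the simulator uses the field's standard
minimal model, a correlated random walk, with the assay's conditioning
dynamics layered on top. Per frame (Δt = 1/fps):

* speed is lognormal with mean `base_speed_mean` (default 25 mm/s, a typical
  adult zebrafish cruising speed) and CV 0.6;
* heading evolves by AR(1)-correlated turning noise,
  `turn_t = ρ turn_{t−1} + σ_r ε_t` with persistence ρ = 0.5 and
  σ_r = `noise_sigma0`·`noise_decay`^r (defaults 0.8 rad, 0.97/run):
  behavioral noise shrinks gradually as training progresses;
* during the sound and gap epochs of run *r* the velocity gains a drift along
  the screen axis of magnitude `gain_max (1 − e^{−r/τ}) a_r` — toward the
  screen under NCF, away under DFM. The saturating learning curve (τ = 3
  runs) makes divergence visible by about the third run and near-maximal by
  the tenth; `a_r` is a sinusoidal attention modulation across runs
  (amplitude 0.3, period 6 runs) capturing waxing and waning engagement;
* if the previous run was aversive, the first `hysteresis_frames` (default
  10, i.e. 1 s) of the gap carry an extra away-drift — the lingering
  avoidance that produces the "region of behavioral uncertainty";
* walls reflect specularly, with an inward bias inside a 15 mm wall margin so
  that edge-tracking occurs without trapping.

The default drift gains (9 mm/s for both cues) are the one calibrated
quantity: they are set so that the frame-pooled directional-bias effect size
between cues in the test runs lands at the published Cohen's d ≈ 0.47, and
then frozen. Inter-individual variability comes from `policy_sampler()`,
which jitters speed, gains and noise lognormally across fish.

What the simulator does *not* emulate: tail-beat kinematics, burst-glide
structure, social interaction, vertical motion, tracking dropouts and
identity switches of real video tracking. Pipeline tests passing on
simulated cohorts therefore validate the analysis chain's correctness and
calibration, not the biological fidelity of any particular parameter value.

### Day-2 consolidation

Overnight consolidation is modelled by `day2_policy()`: turning noise is
multiplied by `consolidation_factor`, the learning and noise schedules are
warm-started at their day-1 terminal run index, and the fish acquires
anticipatory station-keeping — a tonic goal-ward drift (a saturating
fraction, `min(1, 2(1 − factor))`, of the learned gain) outside the cue
epochs of the single-cue day-2 retraining session. The tonic term is needed
because in a bounded tank a pure reduction of turning noise makes paths more
ballistic and *increases* positional spread; empirically, consolidated fish
start trials closer to their learned goal, and that concentration is what
contracts the dispersion trace. Dispersion itself
(`state_space_dispersion()`) is the trace of the covariance of (proximity to
the conditioned goal, yaw) over the sound+gap frames of Block-1 runs — the
trial-locked nascent-state behavior, excluding inter-trial free swim. Raw
units (mm² + rad²) are the default, so proximity dominates; a z-scored
option exists for unit-free comparisons but is uninformative within a single
fish-day (it always totals 2).

## Features and filters

`extract_features()` computes, per (fish, run), on the gap frames:

* **distance from screen** — mean head `x` over retained gap frames (mm);
* **swim activity** — median frame speed over frames faster than 16 mm/s
  (slower successive frames are discarded, as in the assay's filtering
  rule);
* **directional bias** — mean of (per-frame displacement toward the screen ×
  frame speed) over the first 2 s of the gap (mm·mm/s, positive = approach).
  The published bias magnitudes (~±50) are not derivable from the verbal
  definition, so no attempt is made to match them — the definition here is
  dimensionally explicit and its *sign structure* and effect size are what
  the tests check;
* **longest trajectory** — direction (±1) and duration of the longest bout
  of consecutive frames moving in a constant direction along the screen
  axis, tolerating isolated single-frame sign flips (the published
  definition is verbal; the smoothing keeps one-frame tracking jitter from
  splitting bouts).

Edge exclusion discards positions within 10 mm of the back wall and 20 mm of
the screen (a wider 40 mm screen margin is available for density plots,
matching the stricter exclusion used there). Frames are assigned to epochs by
half-open `[start, end)` intervals, so each frame belongs to exactly one
epoch.

Two pooling modes exist because the assay's own analyses use both: per-run
rows (independent units for cohort inference) and per-frame rows (the
descriptive frame-pooled mode used for the discriminant analysis counts).
Frame-level rows are serially dependent and are flagged as such; all
cohort-level conclusions in `run_full()` rest on per-run or per-fish
summaries.

## Density, proportion and the decision zone

`location_density()` is a Gaussian kernel density (default bandwidth 10 mm,
2 mm bins) of distance-from-screen per cue, renormalized over the analyzed
range. `proportion_curve()` converts the pair into the NCF occupancy share;
the per-cue densities each integrate to 1, so they are re-weighted by their
frame counts (with equal counts this reduces to the plain density ratio).
Bins with joint density below 1% of the uniform level are flagged undefined
rather than returning noise-dominated ratios.

The decision zone — the band where occupancy shifts steeply between cues —
is detected by a gradient-quantile rule: the maximal contiguous interval
where |dp/dx| exceeds the 0.75 quantile of its own distribution, required to
contain the global maximum-gradient bin. The published zone was identified
by inspection; the quantile rule is a reproducible surrogate with the
threshold exposed in the interface. A flat curve yields an explicit "no
zone" result. `uncertainty_region()` compares two blocks' proportion curves
and returns the intervals where they diverge by more than a tolerance
(default 0.05) plus the integrated divergence.

## Inference layer

All statistics the assay relies on are implemented from first principles and
cross-checked in the tests against independent oracles (full enumeration,
analytic identities, `stats::manova`, `stats::wilcox.test`,
`car::leveneTest`, `pROC::auc`):

* **Fisher discriminant analysis** on (distance, activity, bias):
  Wilks' Λ = det(W)/det(W+B); for two groups the exact transform
  F = (1−Λ)/Λ·(N−p−1)/p on (p, N−p−1) degrees of freedom (identical to
  Hotelling's T²); canonical direction `W⁻¹(μ₁−μ₂)`; resubstitution
  misclassification under the pooled-covariance linear rule with
  proportional priors; ROC AUC of the canonical score; −2 log-likelihood of
  the Gaussian discriminant model (reported for parity, not used for
  decisions).
* **Wilcoxon tests**: signed-rank (statistic = positive-rank sum) and
  rank-sum, exact by full enumeration up to 12 observations, tie-corrected
  normal approximation with continuity correction beyond; zeros dropped,
  mid-ranks for ties (the source analyses do not state their tie policy, so
  the standard one is used and documented). Rank-biserial effect size
  r_rb = (2W − ΣR)/ΣR for paired data and 2·AUC − 1 for two samples.
* **Brown–Forsythe (median-centered Levene) test**, mean-centered optional.
* **Cohen's d** with n−1 pooled variance.
* **Rank-based AUC** via the Mann–Whitney identity (ties count half).
* **Second-level per-fish tests**: frame data collapse to per-fish per-cue
  medians and a signed-rank test runs across fish — the route around
  frame-level pseudo-replication.

The degrees of freedom (3, N−4) for the two-group DA reproduce the published
parameterization (220 pooled rows → F(3, 216)).

## Numerical and degenerate-input choices

Epoch boundaries are half-open toward the later epoch. Envelope segmentation
merges gaps shorter than 50 ms and reports nothing for silence. A decision
zone is "not found" (not an error) when the maximum gradient is below 1e−6
per mm. Identical per-fish cue medians yield a degenerate second-level test
with p = 1 and r_rb = 0 instead of an error, as do identical day-1/day-2
dispersion traces. All simulator randomness flows through R's RNG, so a
single seed fixes a whole cohort; per-fish seeds are drawn from the master
seed, and replicate experiments use disjoint seed offsets.

## Problem sizes used in validation

The packaged validation runs use 21-fish cohorts under the full session
timeline (18 runs, 100–200 s inter-trial intervals, ~39,000 frames per fish):
200 replicate cohorts for the null-calibration check (empirical type-I rate
of the per-fish discrimination test at α = 0.05), 100 for detection power and
effect-size recovery, 100 fish for the consolidation contraction rate and 30
seven-fish two-day cohorts for the rank-biserial recovery, and 100 random
tables for the discriminant-analysis oracle equivalence. These sizes give
binomial standard errors of 1–4 percentage points on the reported rates.

## Known limitations

* The simulator's movement model is deliberately minimal; its parameters are
  plausible rather than fitted to data, and hence recovered *magnitudes*
  (medians, variances) are not comparable to the published real-data values —
  only signs, calibration rates and effect-size targets are.
* The published headline statistics (Λ = 0.942, W = 58,179.5, AUC = 0.634,
  the group-mean table) were computed on tracking data that are not publicly
  deposited; this package reproduces their structure, not their values.
* Directional-bias units follow the explicit definition here and differ from
  the published table's unstated normalization.
* The decision-zone rule depends on the gradient quantile and KDE bandwidth;
  both are exposed, and the defaults are validated only on the logistic
  fixture and simulated cohorts.
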