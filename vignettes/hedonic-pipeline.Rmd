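---
title: "From sensor kinetics to odor pleasantness: the hedonose pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sensor kinetics to odor pleasantness: the hedonose pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedonose)
```

## The problem

Human odor perception is organized around a dominant hedonic axis:
the single question "how pleasant is this smell?" explains more of the
perceptual variance between odorants than any other descriptor. If
pleasantness is substantially written into the physicochemical makeup of
a stimulus, then a non-specific chemical sensor array — an electronic
nose — should be tunable to predict it, for odorants it has never
sampled and raters it has never met. This package implements that
tuning end to end and, because raw instrument recordings are bulky and
instrument-specific, ships a generative model of both the sensors and
the raters so that every stage can be exercised and tested on data whose
ground truth is known.

## The measurement model

One measurement is a 30-second headspace injection observed by 16
sensors: 8 quartz-microbalance (QMB) sensors, whose resonance shift
tracks adsorbed mass, and 8 heated metal-oxide (MOX) sensors, whose
resistance tracks redox reactions. Each sensor yields a time series with
a characteristic morphology — flat baseline, saturating rise while the
analyte flows, slow exponential return. Absolute response amplitudes are
unreliable: vapor concentration above the liquid sample fluctuates
between runs even at fixed liquid concentration, scaling all 16 traces
of a measurement together. The *pattern* across sensors is what carries
odorant identity.

### The 120-feature signature

`extract_features()` reduces each trace to four kinetic parameters —
maximum response (after baseline correction), latency to the first
maximum, and the two half-maximum crossing times on the rise and the
decay — and appends all 28 unordered pairwise ratios of the 8 MOX maxima
and the 28 QMB ratios: 16 × 4 + 28 + 28 = 120 features. The ratios are
invariant to the shared concentration gain by construction, which is the
point of including them.

Numerical conventions, chosen once and fixed:

* **Baseline**: mean of the first 5 samples, subtracted. The window must
  precede injection onset; the synthetic generator leaves 30 s of
  pre-injection baseline so this holds by construction. `baseline_n = 0`
  disables correction.
* **Half-max crossings**: first crossing on each side of the peak,
  linearly interpolated between samples. First-crossing is the
  deterministic choice when noise makes a trace cross half-max more than
  once.
* **Never-decaying traces** (half-max not reached again before the
  recording ends): the decay time is set to the last timestamp and the
  trace is flagged `decay_truncated`.
* **Degenerate traces** (constant, or never above baseline): zero
  maximum, all three times set to the peak time, flagged. The ratio
  floor `epsilon = 1e-9` keeps ratios finite and positive when maxima
  are zero.
* **Ratios** use baseline-corrected maxima and the fixed orientation
  `(m_i + eps) / (m_j + eps)` for pairs `i < j` in lexicographic order;
  C(8,2) = 28 forces unordered pairs.

### Normalization

`normalize_features()` performs two steps: feature columns are z-scored
(mean 0, SD 1; constant columns are zeroed), then signature rows are
scaled to unit Euclidean norm. The column step stops any single sensor
or unit system (seconds vs. response units) from dominating; the row
step removes per-measurement gain. Column statistics fitted on a
training set are frozen and re-applied to novel-odorant matrices —
prediction must never refit preprocessing on test data.

The order of the two steps is genuinely open, and the two orders have
different exactness properties. Normalizing rows *first* cancels a
purely multiplicative per-measurement gain exactly (if two rows are
proportional they become identical); once columns have been centered the
cancellation is only approximate, because centering mixes rows. We keep
columns-first as the default — on generated benchmarks it performs
slightly better downstream (held-out r higher by ≈ 0.02–0.08 across
seeds), and the resulting signatures are z-scored cosine directions,
which is the cleaner geometry for the nearest-centroid QC — and expose
`order = "rows_columns"` for the exact-cancellation variant. In
practice the distinction is minor: of the 120 features only the 16
maxima carry gain at all; the timing and ratio features are
gain-invariant before any normalization.

## Quality control

Repeated measurements of one odorant should cluster. `cluster_qc()`
assigns every sample to the nearest class centroid (Euclidean distance
on the normalized matrix; with unit-norm rows this ranks identically to
cosine similarity), with the sample's own class centroid computed with
the sample held out — otherwise a sample drags its own centroid toward
itself and outliers are never caught. Samples assigned to a foreign
class are removed. A class reduced to a single repetition has no
held-out centroid; its sample is kept and flagged rather than judged by
an undefined criterion. On default synthetic benchmarks with a 10%
failure rate, scrambled measurements are caught at sensitivity ≥ 0.8
while clean samples are retained at specificity ≥ 0.9.

## The hedonic model

Ratings sit on a 0–30 visual-analogue scale whose midpoint separates
unpleasant from pleasant. The model's target is the per-odorant median
of all ratings (both sessions pooled; even-count medians are the mean of
the middle pair), centered by subtracting 15 so that the sign of a
prediction is its hedonic class. Centering at the scale midpoint is the
pivotal convention — the classification rule "positive predicted value =
pleasant" and the symmetric exclusion bands (14–16 … 10–20) both assume
it — and it is configurable only in the sense that the caller supplies
the centered targets.

The regressor is deliberately small: a three-layer feed-forward network
(120 inputs, 5 tanh hidden units, linear output) trained by full-batch
gradient descent for 20 epochs. A single such run is a weak, noisy
learner; the predictor is the **average of 20 runs** from independent
random initializations, which cancels initialization noise while
retaining the learned signal. Training rows are individual measurements
(each carrying its odorant's target — the repetitions are the model's
noise augmentation), and per-odorant predictions average over retained
repetitions; averaging per odorant never hurts held-out correlation on
average, and usually helps.

Trainer hygiene, all undone transparently at prediction time: targets
are divided by 15 to sit in roughly [−1, 1], and the unit-norm input
signatures are multiplied by √120 so individual features are O(1) — the
scale a fixed-step trainer is calibrated for. Without the input
rescaling, features of magnitude 1/√120 leave full-batch descent an
order of magnitude short of its plateau after 20 epochs (held-out r
0.2–0.7 across seeds against a ridge-regression ceiling of ≈ 0.9 on the
same folds). With it, defaults `learning_rate = 0.2`, `init_scale = 0.2`
put the descent on its plateau by about epoch 10, which is why the
result is insensitive to epochs anywhere in 10–30 and hidden layers of
3–10 units (verified in the test suite), while staying well below the
divergence threshold near learning rate 1. Weight initialization is
uniform in ±`init_scale`.

## The evaluation battery

* **Leave-group-out CV** (`leave_group_out()`): hold out a random group
  of odorants — all repetitions leave together, so no signature of a
  test odorant ever appears at training — train the ensemble on the
  rest, correlate held-out per-odorant predictions with their medians.
  Pearson p-values use the two-sided t transform with df = n − 2 (via
  `stats::cor.test`); the suite checks this against a 10,000-shuffle
  permutation null. Both mean and median p are reported, since the mean
  of p-values across repeats is a fragile summary.
* **Classification with exclusion bands** (`exclusion_sweep()`): sign
  agreement between prediction and `median − 15`, scored outside a
  mid-scale band; the default grid of symmetric bands (15 − k, 15 + k),
  k = 0…5, runs from "none" to 10–20. Odorants near the hedonic midline
  are genuinely ambiguous — their exclusion asks the device only to
  separate clearly pleasant from clearly unpleasant. Per-measurement
  accuracy is available as a secondary output (predictions repeat per
  measurement, so the two bookkeepings differ).
* **Permutation null** (`permutation_control()`): scramble the
  odorant-to-pleasantness assignment, rerun the *entire* train/test
  protocol, repeat 100 times. The mean scrambled correlation sits at
  zero (|mean r| well under 0.05 on the default benchmark); anything
  else would mean the pipeline manufactures structure from noise.
* **Power curve** (`power_curve()`): fixed held-out test set, training
  subsets of increasing size; reports mean r and the fraction of
  non-significant runs per size. On default synthetic benchmarks,
  training sets of ≤ 10 odorants are reliably underpowered.
* **Agreement statistics** (`agreement_stats()`): three human-agreement
  quantities that are routinely conflated are computed and named
  separately — mean pairwise subject–subject correlation, mean
  subject-to-median correlation, and mean within-subject test–retest
  correlation — plus the machine-to-median correlation and the
  machine/human percent, `100 · r_machine / r_subject_to_median`,
  truncated toward zero by default (`method = "round"` switches to
  rounding; printed percentages in the field use both conventions
  inconsistently, so the convention is explicit here).

## The synthetic study

`simulate_study()` bundles three generators whose defaults are the
benchmark conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_odorants` | 76 | training-library size |
| `d` | 10 | latent descriptor dimension |
| `slope` | 6 | VAS units per descriptor SD along the hedonic axis |
| `reps` | 5 | repetitions per odorant |
| `sigma_add` | 0.02 | additive trace noise SD (response units) |
| `sigma_mult` | 0.1 | SD of the shared concentration gain factor |
| `failure_rate` | 0 | fraction of pattern-destroying failures |
| `n_subjects` | 15 | raters per cohort |
| `sigma_subj` | 6 | subject noise SD (VAS units) |
| `gamma` | 0 | scale-usage distortion (0 = linear scale use) |

Each odorant is a standard-normal latent descriptor; true pleasantness
is `15 + 6 · (w · descriptor)` clipped to [0, 30], which spans most of
the scale while keeping clipping rare. Sensor amplitudes are
`softplus(g_s · descriptor)`, modulated by one multiplicative gain per
measurement (shared across sensors — exactly the nuisance the row
normalization targets). The per-sensor gain vectors are constructed so
their sum is orthogonal to the hedonic direction `w`: total response
magnitude then carries no first-order pleasantness information, and the
generated data reproduce the empirical observation that both pleasant
and unpleasant odorants produce both strong and weak responses
(|r| < 0.2 between summed amplitude and pleasantness, tested). Traces
follow a saturating rise (during a 30 s injection starting at t = 30 s
on a 0–300 s, 1 Hz grid) and exponential decay, continuous at the
injection end; QMB time constants are drawn faster than MOX
(rise 4–8 s vs. 8–15 s), echoing mass loading vs. heated-surface
chemistry. Instrument failures are modeled as re-randomized amplitude
vectors — the minimal model that destroys the odorant pattern while
keeping a plausible-looking trace, which is precisely what a clustering
QC can and should catch.

Raters draw `N(0, sigma_subj)` noise independently per subject ×
odorant × session; `sigma_subj = 6` reproduces per-odorant
across-subject SDs near 6, the magnitude typical of mid-scale-using
cohorts on a 30-point VAS. A cohort with `gamma > 0` passes its latent
rating through `15 + (30/π)·atan(gamma·(p − 15))` — an odd, monotone,
saturating distortion parameterized by one number — which pushes
ratings toward the scale extremes and raises per-odorant SDs (near 8 at
`gamma = 0.5`), emulating cohorts that under-use the scale middle. Two
cohorts sharing true pleasantness but differing in `gamma` retain
between-cohort median correlations above 0.7 at these noise levels.

**What the generators do not emulate** — and hence what passing tests do
*not* establish about instrument data: sensor drift across days,
humidity and temperature effects, conditioning and purge-cycle
artifacts, concentration-dependent pleasantness shifts, correlated
(non-spherical) descriptor structure in real chemical libraries, and
stable idiosyncratic preferences (a rater's subject × odorant affinity
that persists across sessions). The last omission means synthetic
test–retest correlations understate real raters', whose session-one
rating predicts session two better than a peer's rating does.

## Problem sizes and determinism

Every stochastic operation takes an explicit integer seed and is exactly
reproducible given it; ensemble members and cross-validation repeats
draw child seeds from the seeded generator, so results are invariant to
evaluation order. The test suite and the acceptance script run the full
pipeline at the study scale it emulates — 76-odorant libraries with 5
repetitions, 20-network ensembles, 20-repeat cross-validations, and the
100-scramble permutation null (2,000 network trainings, a few seconds
on one CPU); the noiseless ceiling benchmarks use 60 odorants. These
sizes are the package's reference conditions, not shortcuts.

## Known limitations

* The latent-descriptor → sensor map is smooth and low-dimensional;
  real sensor chemistry is neither, and absolute performance numbers on
  synthetic benchmarks (held-out r ≈ 0.8–0.9) exceed what mixed
  real-world libraries yield.
* With ~50 training odorants in a 10-dimensional latent space, held-out
  recovery is information-limited near r ≈ 0.9 even with all noise
  sources disabled — a ridge oracle on identical folds hits the same
  ceiling — so "more training odorants" beats "a better learner" in
  this regime, which is exactly what the power curve shows.
* The ensemble regresses onto the median rating of one cohort;
  cohort-specific scale usage is emulated and measured
  (`agreement_stats`) but not corrected for.
* Pleasantness is modeled at a single concentration per odorant;
  concentration-dependent hedonic shifts are out of scope.
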