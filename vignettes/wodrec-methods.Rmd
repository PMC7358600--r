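---
title: "Recognizing functional-fitness drills from inertial sensor data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing functional-fitness drills from inertial sensor data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wodrec)
```

`wodrec` classifies windows of continuous multi-sensor inertial data into
four functional-fitness drills — clean & jerk (`C&J`), american swing
(`AS`), box jump (`BJ`), burpee (`BP`) — and the transition phases between
them (`TRANS`). This vignette is the package's account of the method: the
data model and its conventions, the segmentation and labeling rules, the
feature set, the classifier grid, the evaluation protocols, the mRMR
feature ranking, and the design of the synthetic-workout simulator that
stands in for a recorded dataset. Where a design choice was genuinely open,
the reasoning is given here.

## Data model

A **recording** is one participant's workout set: synchronized tri-axial
accelerometer (g, gravity included) and gyroscope (°/s) streams from up to
five sites (wrist, upper arm, thigh, ankle, lumbar spine) sampled at a
common rate, 148.15 Hz by default, plus an annotation track of movement
intervals. Two conventions are worth stating explicitly:

* **Units and gravity.** Acceleration is stored in g with gravity included,
  as consumer IMUs report it. Nothing in the pipeline subtracts gravity; the
  frequency features instead exclude the DC bin (below) so a standing
  posture does not pin them to 0 Hz.
* **Saturation.** Values are clipped to the physical sensor ranges (±16 g,
  ±2000 °/s) on ingest and on simulation, so reader and simulator honour the
  same contract.

Annotations are half-open intervals `[start_s, end_s)`. Any span not
covered by a movement interval is implicitly `TRANS`: in this protocol the
participant is always either executing a drill or transitioning, so
unannotated time is a transition by definition rather than an error.

The wide signal CSV (one row per sample, `time_s` + `<site>_<quantity>_<axis>`
columns) treats the time column as informative only — the sample index and
the sampling rate are authoritative, which keeps windowing exact under
floating-point time stamps.

## Segmentation and majority labeling

Windows are `floor(window_ms/1000 × fs)` samples long (600 ms at 148.15 Hz
gives 88 samples; flooring never exceeds the nominal duration) and hop by
`round(window_samples × (1 − overlap/100))` samples, ties rounded half away
from zero (88 × 0.9 → 79). A recording of `n` samples yields
`floor((n − w)/step) + 1` windows; trailing samples that cannot fill a
window are discarded, and windows never span two sets.

A window is labeled with a movement class only when that movement covers
**strictly more than** `majority_frac = 2/3` of its samples; otherwise it is
`TRANS`. The published rule says "more than 66%"; we read 66% as two-thirds
and keep `majority_frac` configurable (set `0.66` for the literal reading).
Strictness matters at the boundary: exact two-thirds coverage is a
transition. A consequence of the rule worth knowing: a window straddling
two back-to-back drills can never reach the threshold for either, so
drill-to-drill boundaries are always transitions — this is the dominant
error mode of the whole approach, since up to a third of a window labeled
`TRANS` may contain genuine movement.

Coverage is computed on sample counts against the gap-filled (tiled)
annotation track, which makes labeling invariant to splitting an interval
into adjacent pieces with the same label.

## Features

Each channel (site × quantity × axis) contributes 18 features per window —
11 time-domain and 7 frequency-domain — giving 108 per sensor and 540 for
the full five-sensor setup. Conventions, in order of how often they bite:

* "Mean value" is the plain mean of each axis channel. The alternative
  reading (mean Euclidean norm across axes) would break the
  18-per-channel accounting that yields 540 columns.
* Standard deviation uses the n−1 denominator; the mean absolute deviation
  is about the mean; percentiles interpolate linearly between closest ranks
  (R type 7).
* Kurtosis is the **non-excess** moment estimator (normal ≈ 3), matching
  the convention of the MATLAB toolbox family this pipeline emulates;
  `excess = TRUE` switches. On a constant window skewness and kurtosis are
  defined as 0.
* The spectrum is the one-sided periodogram of the raw window — no
  detrending, no taper, mirroring a pipeline in which kinematic quantities
  are not filtered — with the DC bin excluded and scaled so that total
  power equals the population variance of a zero-mean window (Parseval;
  this is asserted in the tests).
* "Higher/lower frequency" are not standard quantities; they are
  implemented as the extreme frequencies whose power reaches 5% of the peak
  (the fraction is a parameter). Median frequency is the half-power point
  (with a 1e−12 relative epsilon so an exactly 50/50 two-tone spectrum
  resolves to the lower tone); mean frequency is the power-weighted mean.
* Spectral entropy is normalized by `log K` so it lies in [0, 1] and is
  comparable across window lengths. Zero-power (constant) windows return 0
  for all seven spectral features by convention.

Feature columns are ordered deterministically (site in canonical order,
then quantity, axis, feature), and sensor-subset experiments slice the
already-extracted 540-column matrix rather than re-extracting.

Standardization is z-scoring per column with statistics computed on
training rows and frozen for test data; constant columns map to zero. All
classifiers consume standardized features. The published pipeline states
standardization only for the mRMR analysis, so this is a documented choice
(`standardize = FALSE` in the classifier spec switches it off); it cannot
hurt the SVMs and makes the kNN distance metrics scale-free.

## Classifier grid

Six SVM kernels and six kNN variants, matching the preset families of the
original toolbox:

| family | variant | meaning |
|---|---|---|
| SVM | linear, quadratic, cubic | polynomial degree 1/2/3, `coef0 = 1`, box constraint 1 |
| SVM | gauss_fine/medium/coarse | RBF with kernel scale √P/4, √P, 4√P (ratio 1:4:16) |
| kNN | fine / medium / coarse | Euclidean, k = 1 / 10 / 100 |
| kNN | cosine | cosine distance, k = 10 |
| kNN | cubic_distance | Minkowski p = 3, k = 10 |
| kNN | weighted | Euclidean, k = 10, inverse-squared-distance vote weights |

Multi-class SVMs use one-vs-one pairwise voting (10 binary machines for 5
classes, via libsvm through `e1071`); no per-kernel hyperparameter tuning is
done, reproducing default preset behaviour. No class rebalancing is applied
despite the transition-heavy prior (class weights exist as an option but
default off). ROC scores are signed one-vs-rest aggregated pairwise margins
for SVMs and (weighted) neighbour vote fractions for kNN; both are monotone
in class likelihood, which is all a threshold sweep needs.

## Evaluation protocols

* **Stage 1 — stratified 5-fold CV** on the training sets (set1 + set3).
  The fold assignment is stratified by class with a seeded shuffle; the
  original description does not say, but stratification protects the rare
  movement classes (hundreds of windows each against thousands of
  transitions) from starving a fold.
* **Stage 2 — leave-one-subject-out.** For each participant, train on
  sets 1 and 3 of all the others, test on the held-out participant's set 2
  (the workout simulation). Train and test are disjoint by participant and
  by set, by construction; the pooled confusion matrix across iterations is
  reported, with per-iteration accuracies and their mean also available.

Per-class metrics are the one-vs-rest collapses
`ACC = (TP+TN)/total`, `PPV = TP/(TP+FP)`, `TPR = TP/(TP+FN)`,
`FNR = 1 − TPR`, `FPR = FP/(FP+TN)`; zero-denominator cases return 0 with a
degeneracy flag. AUC is the trapezoid rule over the threshold sweep and is
tested against the rank-statistic (pair-counting) identity. Percentages are
displayed to one decimal; tests compare printed values at half a unit in
the last place.

The package ships the benchmark confusion matrices of the reference
configuration (cubic SVM, 600 ms / 10%) as plain-CSV fixtures
(`benchmark_confusion()`), so the metric arithmetic is exercised against
published numbers without any simulation.

## mRMR feature ranking

Features are discretized into 10 equal-frequency bins (robust to the
heavy-tailed, burst-like feature distributions; the bin count is a
parameter) and ranked greedily by mutual information with the label minus
the mean MI with already-selected features — the **MID** (difference)
criterion. MID rather than the quotient criterion because it is the common
default and numerically stable as redundancy approaches zero. Ties break
toward the lower column index, making the ranking deterministic and
permutation-equivariant. The reduced configuration keeps the top 20
features. The composition of the selection (time vs frequency domain,
accelerometer vs gyroscope, per site) is a reporting output
(`ranking_profile()`), not a constraint.

## The synthetic-workout simulator

No public dataset accompanies this recognition task, so the simulator is a
first-class module: every pipeline stage is developed and tested against
generated cohorts whose ground truth is known exactly.

**What it emulates.** The three-set session protocol (set1/set3: 3
repetitions of each of the 4 drills; set2: rounds of 1, 2, 3, 4 repetitions
of each — 40 executions, 10 per drill), back-to-back execution with only
short transitions, per-participant randomized drill order, inter-subject
variability (lognormal tempo, per-site amplitude and frequency scales),
gravity as a per-site constant accelerometer offset with slow orientation
drift, AR(1) posture/movement noise during transitions, white measurement
noise, and range saturation.

**The signal model.** Each drill's signature is a sum of Gaussian-windowed
sinusoid bursts (amplitude; center and width as fractions of the repetition
duration; carrier in the 1–8 Hz band) on a drill-specific subset of
channels: sharp high-frequency impact bursts on ankle and thigh for the box
jump, sustained ~1.4 Hz activity on lumbar spine and arm for the swing, a
biphasic arm pattern for the clean & jerk, and broadband whole-body bursts
for the burpee, each overlaid on whole-repetition oscillation components so
that a window anywhere inside a repetition carries class information. This
is the simplest generator producing drill-distinct envelopes *and* spectra
across sites; the protocol is specified by the study design, but the signal
model is ours.

**Parameters that are choices, not measurements.** Repetition-duration
medians (C&J 3.0 s, AS 1.6 s, BJ 2.2 s, BP 3.2 s; sdlog 0.15, truncated to
[0.8, 6] s), transition durations (median 1.2 s, truncated [0.5, 3] s),
noise levels and all burst parameters are generator defaults chosen to give
plausible, clearly separable dynamics at realistic repetition tempos. They
are documented as simulator parameters; the published duration
distributions are not recoverable from the available text.

**What passing tests do and do not show.** The simulator's acceptance
property brackets its separability dial: the default templates support
leave-one-subject-out pooled accuracy above 0.90 with the reference
pipeline on a 14-participant cohort, while zero-amplitude templates (drills
indistinguishable from transition noise) collapse accuracy to the
majority-class baseline, and label permutation collapses drill recall to
chance. Passing these demonstrates that the pipeline recovers class
structure that is present and finds none where there is none — it says
nothing about accuracy on real recordings, where signatures are less
stationary, sensor placement varies, and labeling itself is uncertain. The
simulator also does not emulate magnetometer data (excluded from the task),
EMG, or hardware artifacts such as dropped samples.

## Numerical and degenerate-case choices

* Window/step arithmetic: `floor` for length, `round` half-away-from-zero
  for step; a recording shorter than one window yields zero windows with a
  warning.
* Constant windows: sd/MAD 0, skewness/kurtosis 0, spectral features 0.
* Standardization: constant columns map to 0 (not NaN).
* kNN: distance ties break by training-row order, vote ties by class order;
  inverse-squared-distance weights are capped at 10^24 (distance floor
  1e−12) so exact duplicates dominate without producing infinities.
* mRMR: duplicate quantile cut points collapse (heavily tied features get
  fewer bins); features with a single bin have zero relevance.
* Per-cell experiment seeds derive from the master seed and the cell
  coordinates, so any grid cell reproduces in isolation; infeasible cells
  (a class rarer than the folds) are recorded as missing, not fatal.

## Problem sizes used in the shipped checks

The test-suite and acceptance script exercise the full pipeline at the
study's own scale — a 14-participant cohort (≈6,500 windows of 540
features at 600 ms / 10%) for the headline leave-one-subject-out and
cross-validation runs — and smaller seeded cohorts (2–5 participants) for
unit and property tests, which keeps the default runs to a few minutes
while every contract is still exercised end to end.

## Known limitations

* The simulator's drill signatures are stylized; real inter-repetition
  variability (fatigue drift, technique differences) is modeled only
  through global tempo/amplitude scales and per-burst jitter.
* "Higher/lower frequency" band edges depend on the 5%-of-peak convention;
  other toolboxes use different definitions, and values are not comparable
  across conventions.
* The majority-labeling rule forces drill-to-drill boundary windows to
  `TRANS`; any downstream consumer counting repetitions should merge
  adjacent windows rather than trust raw window labels.
* mRMR operates on a plug-in MI estimate after discretization; with very
  few windows per class the relevance estimates are noisy, and the ranking
  should be read as exploratory, as in the original analysis.
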