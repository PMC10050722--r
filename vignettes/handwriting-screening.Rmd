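---
title: "Handwriting kinematics as a screening signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handwriting kinematics as a screening signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handkin)
```

## The measurement model

A digital dot-matrix pen samples the pen tip at 100 frames per second
while a participant writes on patterned paper. Each frame carries a
position (mm), a timestamp (ms), an integer tip-pressure level on a
0–1024 scale, and a pen-contact flag. `handkin` treats the *stroke* — a
maximal contiguous run of pen-on-paper samples, delimited by pen lifts —
as the unit of analysis, and each stroke contributes one observation to
every downstream statistic. Per-task annotations (the rater-assigned
task score and the number of strokes) are replicated onto each stroke of
the task, so a stroke's feature vector is complete on its own.

Two validation rules resolve ambiguities the hardware leaves open:
pressure must be zero whenever the pen is off paper, and positive
pressure forces the on-paper state; an on-paper sample with zero
pressure is tolerated and treated as sensor noise. Strokes need at least
two samples because every kinematic quantity is a finite difference;
single-sample contacts are counted and dropped, never silently lost.

Coordinates are stored in the page frame (origin top-left, y increasing
downward, the print/scan convention). Features that depend on visual
orientation — only the tilt angle — flip y into the writer's frame
first.

## The 35 handwriting characteristics

`feature_names()` enumerates the canonical set: 33 objective
characteristics plus the task score and stroke count. The objective set
covers five families:

* **Pressure** — population mean, variance, SD and Shannon entropy of
  the per-sample pressure levels within a stroke.
* **Timing** — stroke contact time, and the in-air time preceding each
  stroke (0 for the first stroke by convention).
* **Geometry** — path length; summed absolute horizontal/vertical
  displacements; within-stroke population variance/SD of the per-sample
  absolute displacements; and the tilt of the first principal axis of
  the point cloud against the horizontal, in (−90°, 90°], ascending
  strokes positive.
* **Velocity** — speed is the Euclidean norm of the component
  velocities `vx = dx/dt`, `vy = dy/dt` (dt in seconds, no smoothing by
  default; a centered window-3 moving average is available behind the
  `smooth` flag). Reported are mean speed, mean absolute component
  velocities, extrema/variance/SD of speed and of |vx| and |vy|, the
  Shannon entropy of the speed series, and the slowdown count.
  Absolute component velocities are used for means and extrema because
  signed components cancel on round trips.
* **Acceleration** — the first difference of speed over the midpoint
  time grid; its entropy and slowdown count. A two-sample stroke has an
  empty acceleration series, whose entropy and slowdown count are
  defined as 0.

Three estimator choices deserve justification because the conventional
descriptions leave them open:

* **Entropy.** Shannon entropy in bits over an equal-width histogram on
  `[min, max]` with 16 bins by default (`n_bins` is configurable). A
  constant series has zero entropy. Entropy with a fixed bin *count* is
  invariant under affine rescaling of the series, which makes it a pure
  stability measure.
* **Slowdowns.** A "slowdown" is one deceleration *episode*: a maximal
  run of negative first differences. Counting episodes rather than
  samples matches the intuition of "number of times the pen slowed".
* **Dispersion unit.** The horizontal/vertical length variance/SD are
  computed *within* the stroke over per-sample absolute displacements,
  because the stroke is the analysis unit; an across-stroke reading is
  computable from the feature table if wanted.

Population (divide-by-n) moments are used throughout for per-stroke
dispersions: a stroke is a complete observation window, not a sample
from a longer one.

## The synthetic cohort generator

No public corpus of dot-matrix pen recordings with diagnostic labels
exists, so the package ships a generator whose defaults encode the group
contrasts consistently reported for early Alzheimer's handwriting:
patients write more slowly, with higher and more variable pressure,
pause longer and more often in the air, fragment writing into more
strokes, show larger tremor, score lower on the writing tasks, and score
far lower on MoCA-BC/MMSE (the generator draws AD MoCA-BC around 14.9
versus 28.9 for controls, matching the direction and scale of published
screening cohorts). Magnitudes sit at the scale of published per-stroke
medians: speeds around 10–15 mm/s, pressure levels around 550–650,
in-air times of roughly 0.2 s (controls) versus 0.5 s (patients).

Mechanically, a stroke follows a stylized task template (a plus and
cross of connected points; two intersecting pentagons drawn edge by
edge; word-like glyph groups) with per-segment speed drawn from a
log-normal (positive by construction), per-sample pressure from a
normal clamped to [1, 1024], and inter-stroke gaps from exponential
pause durations, a fraction of which (the profile's `pause_rate`) are
genuine hesitation pauses rather than short pen transits. Scores are
drawn from per-task distributions over the attainable range (task 1 is
scored out of 2, task 2 out of 3, the word tasks one point per word).

Two modelling details matter more than they look:

* **Tremor is band-limited.** Tremor enters as a smooth 4–7 Hz
  oscillation of amplitude `tremor_sd`, the physiological tremor band —
  not as per-sample white jitter. White noise of amplitude `a` at a
  100 Hz frame rate would add an apparent speed of order `a·√2/dt`
  (~25 mm/s at the AD amplitude), swamping and even inverting the
  intended slow-writing contrast.
* **Writers are heterogeneous.** Each record draws a writer-level speed
  multiplier and pressure offset shared by all its strokes. This makes
  strokes within a record correlated, as in real cohorts, and is what
  makes the distinction between stroke-level and participant-grouped
  cross-validation folds meaningful (see below).

Randomness is reproducible and order-independent: every record derives
its own Mersenne-Twister substream from a hash of
`(seed, participant, task)`, so generating a cohort in any order, or a
single record in isolation, yields bit-identical samples. Tasks are
drawn independently within a participant; no within-writer correlation
across tasks is modelled, which mainly affects analyses that pool tasks.

What passing tests on this generator shows — and what it does not: the
pipeline recovers injected effect directions, keeps nominal type-I error
on null cohorts, and separates groups when the contrasts are strong. It
does not show that real patients are classifiable at any particular
accuracy; synthetic contrasts are cleaner than clinical ones, and
near-perfect synthetic AUCs should be read as machinery checks, not
clinical claims.

## Screening statistics

For each (feature, task) pair the two groups are compared with either a
pooled-variance Student *t* test or a Mann–Whitney *U* test. The gate
mirrors common clinical-statistics practice: the parametric test is used
only when both groups pass Shapiro–Wilk at α = 0.05 *and* a
median-centered Levene check finds homogeneous variances; groups smaller
than 3 or constant fall through to the rank test. Missing values are
imputed with the observed column mean (within feature and task) before
testing; this preserves the observed mean exactly and is flagged in the
output. All tests are two-sided; no multiplicity correction is applied
by default (Benjamini–Hochberg is available behind `adjust = "BH"`).

The *U* statistic uses midranks for ties. Its p value comes from the
tie-corrected normal approximation with a 0.5 continuity correction; for
pooled sizes up to 10 an exact two-sided p is computed by enumerating
every assignment of the pooled midranks. The approximation's worst-case
two-sided deviation from exact enumeration, measured exhaustively, is
about 0.017 at 5+5 and grows toward 0.13 for the smallest partitions —
small-sample p values should always come from the exact mode, which is
why it is the default there.

Strokes are pooled as independent observations by default, matching the
stroke-as-sample design. Because strokes within a writer are correlated,
pooled stroke-level tests are anti-conservative for writer-level claims;
`unit = "participant"` first averages each writer's strokes and tests
the per-writer means. The package's calibration checks use the
participant unit for exactly this reason, and it is the mode to use for
honest inference about groups of people.

## Diagnostic evaluation

ROC construction is self-contained: thresholds sweep the unique scores
(rule: score ≥ threshold predicts AD), tied scores collapse into single
steps, and AUC is the trapezoidal area — numerically identical to the
normalized Mann–Whitney statistic, a property the tests verify
exhaustively for all small score/label patterns. The operating point is
chosen by Youden's method (maximal J = Se + Sp − 1), with ties broken
toward the lower threshold, i.e. toward sensitivity — the right bias for
a screening instrument. Accuracy, Se, Sp, PPV and NPV are reported at
that threshold; ratios with empty denominators are NaN with a note
rather than silently dropped.

The classifier roster mirrors the seven models standard in this
literature: logistic regression, k-nearest neighbours (k = 5),
radial-kernel SVM, Gaussian naive Bayes, random forest (200 trees),
gradient-boosted trees (60 rounds, depth 3), and AdaBoost over decision
stumps (50 rounds, implemented on rpart stumps with the classic
weighted-error update). Features are standardized with training-fold
moments; scores are each model's probability-like output, so monotone
calibration differences cannot change AUC.

The evaluation protocol is deliberately explicit, because published
tables in this area often leave it unstated and training-set ROC can be
wildly optimistic. The default is stratified 5-fold cross-validation
with pooled out-of-fold scores. Two switches cover the alternatives:
`protocol = "resubstitution"` scores the training data (to mirror what
optimistic published operating points appear to do), and
`groups = participant_id` keeps all strokes of a writer in one fold.
The leakage is not hypothetical: on null cohorts (identical generating
profiles) with ungrouped stroke-level folds, flexible learners reach
mean AUC ≈ 0.55 purely by re-identifying writers; with grouped folds
the same learners sit at 0.50 as they should.

## Numerical and interface choices

* Timestamps are integer milliseconds; irregular sampling gaps are used
  exactly as recorded, never resampled.
* CSV serialization prints coordinates with `%.17g` and parsing uses
  strtod, so write→read round-trips are bit-exact; the JSON dialect uses
  17 significant digits for the same reason.
* `screen_features` is fully deterministic; `run_classifiers` seeds fold
  assignment and every stochastic learner from its `seed` argument and
  records it in the report.
* Degenerate inputs are first-class: empty files warn and return empty
  lists; a record with no segmentable strokes yields an empty feature
  table with a warning; a feature entirely missing in one group is
  marked untestable rather than imputed into existence; a failing
  classifier adapter yields a `failed` report row without stopping the
  harness.

## Problem sizes used in the checks

The package's own validation uses synthetic cohorts of 12 writers per
group (about 120 strokes per group) for the 1,000-replicate type-I
calibration, 40 writers per group for null-AUC checks, and roughly 500
strokes per group for effect-recovery checks; the bundled
reproduction script runs a full 34 + 45 writer, four-task study. These
sizes keep every check at the scale of the motivating study design
while remaining cheap enough to run routinely.

## Known limitations

* Task templates are stylized polylines; they reproduce stroke-level
  kinematic structure, not legible glyphs, and cannot exercise
  recognition-based scoring.
* The generator draws tasks independently within a writer and models
  writer heterogeneity with two parameters (speed multiplier, pressure
  offset); real within-writer structure is richer.
* Pooled stroke-level screening inherits the anti-conservativeness of
  treating correlated strokes as independent; use the participant unit
  when the claim is about people rather than strokes.
* Mean imputation is the documented convention here; it shrinks
  variances and is only sensible at the low missingness rates typical
  of pen recordings.
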