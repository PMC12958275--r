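---
title: "Movement segmentation and motor-status estimation from wearable IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement segmentation and motor-status estimation from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(segmotor)
library(dplyr)
```

## The problem

After a stroke, upper-limb motor deficits are scored in the clinic with
instruments such as the Fugl-Meyer Assessment (FMA-UE, 0–66) and the Wolf
Motor Function Test (performance time and functional ability score). These
assessments need a trained clinician and a dedicated visit, so they are
administered rarely. Wrist-worn inertial sensors promise a continuous,
objective alternative, but simple activity counts correlate poorly with
impairment — largely because of learned non-use: people can move more or
less than their capacity allows.

Movement segmentation addresses this by decomposing the continuous wrist
velocity into *movement segments* — sign-constant excursions of one velocity
component between consecutive zero crossings — and describing their
kinematics. Healthy point-to-point movements have smooth, bell-shaped speed
profiles; impairment fragments them into overlapping submovements, slows
them, and makes them jerky. `segmotor` implements the two segmentation
strategies in use:

* **Anatomical segmentation** expresses wrist velocity in the trunk's body
  frame (using a second, sternum-worn IMU) and segments each anatomical axis
  independently. All movement, straight or curved, contributes.
* **Linear segmentation** uses only the wrist sensor. Straight
  point-to-point movements (reach, transport, retract) are located — either
  from manual annotations or by a convolutional window detector — velocity
  is projected onto the first principal axis of the movement, and the
  projection is segmented at zero crossings.

Downstream, both feed the same assessment: per-segment kinematic features,
subject-level aggregation, split-half reliability filtering, and a small
sigmoid-output regressor trained to rank subjects like the clinical scores
do.

## Preprocessing model

Both 6-axis streams (3-axis acceleration in m/s², 3-axis angular velocity in
rad/s, 50 Hz) are low-pass filtered with a 6th-order Butterworth at 10 Hz.
All Butterworth stages are applied forward and backward (zero phase): the
segment boundaries are zero crossings, and preserving their timing matters
more than causal filtering. Each pass starts from the filter's steady state
for the first sample, with short odd-reflection padding, so edge transients
are bounded and deterministic.

Orientation is estimated without a magnetometer (indoor environments make it
unreliable) by gradient-descent accelerometer–gyroscope fusion with gain
β = 0.1 rad/s, quaternion-valued (Hamilton convention, scalar first),
mapping each sensor's local frame to a gravity-aligned global frame (z up).
The initial attitude is taken from the first second's mean accelerometer
vector, with zero initial yaw. Heading is unobservable without a
magnetometer: it is held by gyroscope integration alone and drifts slowly
under sustained motion. Tilt, which determines gravity removal, stays
accurate to about a degree at realistic noise; tests assert a 3° bound.

Gravity is removed by rotating wrist acceleration into the global frame and
subtracting each axis' mean. For the anatomical method the result is rotated
into the trunk frame by the inverse sternum orientation and low-pass
filtered once more with the same 10 Hz filter (the second smoothing stage
is exposed as `second_lowpass`). Velocity comes from per-axis
trapezoid integration followed by a 2nd-order 0.1–10 Hz Butterworth
band-pass that suppresses integration drift.

One consequence worth knowing: the 0.1 Hz high-pass blocks DC, so an
*isolated* movement pulse is flanked by a slow, shallow counter-movement
undershoot whose area balances the displacement, and the pulse itself loses
part of its integrated area (about 20% for a 1-s reach in an otherwise quiet
record). In continuous recordings the undershoots of successive movements
merge into the rest-period texture and mostly fall below the quality
filters, but tests on single-pulse fixtures assert the dominant segment with
a matching tolerance rather than exact displacement.

## Segmentation rules

`segment_zero_crossings()` treats samples with |v| below 10⁻⁴ m/s as
crossings; such samples terminate the current segment and belong to neither
neighbour, so segments exactly tile the non-zero support (a property test
checks this against a brute-force sign-run scan). Boundaries sit on the
first sample after the sign change; no sub-sample interpolation is done, so
the duration error is at most one sample. Segments lasting ≤ 50 ms or
travelling < 1 mm are discarded as sensor noise; both boundaries are
asserted in the tests exactly as stated (50 ms inclusive removal, 1 mm
inclusive retention).

The linear method's primary direction is the first eigenvector of the 3×3
velocity covariance within a detected or annotated interval, with its sign
fixed so the mean projected velocity is non-negative. Because PCA is
rotation-equivariant, segment durations and displacements are invariant to
any fixed rotation of the global frame — asserted in the tests.

## Window detector

The detector for straight-path movements consumes 3-s sliding windows
(150 samples, 1/3 overlap between adjacent windows) of the six local-frame
channels. A window is positive exactly when an annotated movement lies
entirely within it. The network has three convolutional layers of 30 filters
(kernel 11), each followed by ReLU and batch normalization, with 2×2
max-pooling after the first two, then global average pooling and a softmax
pair; it is trained with Adam (batch 8, learning rate 10⁻³, 30 epochs by
default). Max-pooling follows the first two convolutional layers only; the
third convolution feeds global average pooling directly. The
network and its optimizer are implemented in R with im2col matrix products;
training is seeded and deterministic. The decision boundary is tuned on the
validation windows to maximize precision, ties broken toward recall, and
positive windows that overlap or abut are merged into maximal intervals.

## Features and reliability

Each segment yields 15 features: mean, SD, max, RMS and coefficient of
variation of speed; mean absolute and maximum acceleration and jerk (first
and second finite differences of the profile); absolute displacement and
duration; and four morphology measures — temporal skewness of the speed
curve, the number of speed peaks with prominence ≥ 5% of the segment
maximum, the speed metric (mean/peak speed, 8/15 ≈ 0.533 for an ideal
minimum-jerk bell), and the jerk metric (−mean |jerk| / peak speed). Mean
speed and mean absolute acceleration/jerk are trapezoid time-averages, so
the ideal-bell value is met at 50 Hz. Skewness is computed over *time*
(third standardized moment of time weighted by speed), which is zero for a
time-symmetric bell; computing it over the distribution of speed values is
the other defensible definition, and the choice is recorded here.

Subject-level vectors take six aggregations (mean, SD, IQR, 10th/50th/90th
percentiles) of each per-segment feature plus the segment rate, i.e.
15 × 6 + 1 = 91 named values in a stable order.

Reliability filtering simulates test–retest from one session: each
recording is split at its temporal midpoint, the full segmentation and
feature pipeline runs independently on each half, and each feature's
ICC(3,1) (two-way mixed, single measurement, consistency) is computed across
subjects between halves. Features with ICC ≥ 0.75 (inclusive) survive. The
split is by time, not by segment count, matching the temporal phrasing of
the protocol.

## The assessor and its loss

The regressor is a linear map from the z-scored reliable features to one
sigmoid-squashed output in [0, 1] (higher = better motor status); a hidden
layer is available behind the `hidden` argument but off by default, reading
"an input layer and an output layer" literally. The training loss is
1 − ρ̄, where ρ̄ is the average Spearman correlation of the predictions
with FMA-UE, *negative* median WMFT performance time, and WMFT-FAS —
clinician-scored measures only; the self-reported MAL scales are excluded
from training but evaluated. Spearman correlation is not differentiable, so
training uses a soft-rank surrogate: prediction ranks are softened by
pairwise sigmoid comparisons at temperature τ = 0.1, target ranks stay
exact, and the surrogate approaches exact Spearman as τ → 0 (tests bound
the gap and check the analytic gradient against finite differences). All
reported correlations use exact Spearman.

Evaluation is nested leave-one-subject-out cross-validation: the outer loop
holds one subject out; the inner loop selects the Adam learning rate from
five log-spaced points in [10⁻⁴, 10⁻²] by pooled held-out validity; the
final model refits on all training subjects (batch 8, 30 epochs by default)
and scores the held-out subject. Fold lineage is recorded and tests assert
that no test subject ever enters its own training matrix. Output
reliability applies each outer-fold model to the test subject's two
temporal-half feature vectors and takes the ICC(3,1) of the resulting pairs
— the fold model is reused, not retrained per half. NRMSE against FMA-UE
rescales the unit-interval estimate by 66 (both scales share the
higher-is-better orientation).

## The synthetic cohort generator

No reference dataset ships with the package; instead it provides a seeded
generator whose output carries the statistical structure the pipeline
assumes, making every stage testable end to end:

* Wrist trajectories are sequences of straight reaches, curved
  multi-direction movements, and rests. Reaches come in out-and-back pairs
  (transport to and retrieval from a target are each a straight movement),
  and curved blocks close on themselves, so the workspace stays bounded and
  the velocity carries little sub-0.1 Hz content — as in real activities of
  daily living.
* A straight reach at impairment θ ∈ [0, 1] is a single minimum-jerk pulse
  when θ = 0, and fragments into 1 + ⌊4θ⌋ submovements as θ rises:
  submovements overlap in pairs (multi-peaked profiles) and successive
  pairs are separated by small corrective reversals, which produce genuine
  zero crossings. Durations stretch by 1/(1 − 0.5θ); movement-frequency
  velocity irregularity (2–3.5 Hz, multiplicative, amplitude 0.45θ) and
  tremor (4–7 Hz, additive, 0.08θ m/s at θ = 1) grow with θ.
* Both IMUs are forward-simulated: wrist local acceleration is the
  trajectory acceleration plus gravity rotated into a slowly drifting local
  frame (tilt-only initial attitude), the gyroscope reads the local-frame
  angular velocity, and the sternum carries slow torso sway and yaw. White
  Gaussian sensor noise defaults to 0.05 m/s² and 0.01 rad/s.
* Clinical scores are monotone noisy maps of θ: FMA-UE = 66(1 − θ) + ε
  with ε ~ N(0, 3), WMFT time increasing in θ, the 0–5 scales decreasing,
  with proportionally scaled noise.
* Default cohorts have 17 subjects with θ uniform on [0.05, 0.9] — a
  realistic size for clinical cohorts of this kind, small enough that
  leave-one-subject-out behaviour matters.

What the generator does *not* emulate: biomechanical joint constraints,
hand/finger dexterity, gyroscope bias and scale error, magnetic disturbance,
task-specific movement vocabularies (task names are labels only), or the
empirical distribution of real ADL kinematics, for which no quantitative
reference is available. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that it recovers a known impairment
signal under its own assumptions — not that any particular clinical
cohort's correlations are reproduced.

One generator-specific finding is recorded here because it shaped a test:
the pooled median of the speed metric is *not* monotone in θ, because
fragmentation floods the segment pool with short pieces whose mean-to-peak
ratio is high; the degradation is monotone in the jerk metric and in the
speed metric of segments travelling at least 5 cm, and those are what the
smoothness test asserts.

## Problem sizes, tolerances, numerical choices

The test suite and the acceptance script run the full pipeline at reduced
but honest sizes chosen as the package's own defaults for its checks:
17-subject cohorts at 60–90 s per subject (reliability filtering and
parameter recovery), 6-subject cohorts at 90 s for the experiments, 10
training epochs for cross-validated fits inside loops (30 remains the
user-facing default), and a 5-point learning-rate grid. At these sizes the
nested LOSOCV recovers |Spearman| ≥ 0.7 against the synthetic FMA-UE in 9
of 10 seeds, and permuted-score runs center near zero.

Other numerical choices: zero-crossing tolerance 10⁻⁴ m/s (configurable);
exact-zero samples belong to no segment; peak prominence 5% of the segment
maximum (this package's definition); degenerate inputs error
early (all-zero accelerometer, zero-variance PCA windows, constant inputs
to correlation statistics); constant predictions make the rank loss
degenerate and are reported as loss 1 with a warning; batches smaller than
4 are folded into the previous batch so within-batch rank correlations stay
defined. Steiger's z for comparing dependent validity correlations uses
Fisher transforms with the pooled-correlation covariance; it is applied to
Spearman coefficients as a deliberate fidelity choice even though the
asymptotics are nominally Pearson.

## Known limitations

* Heading drift: without a magnetometer, yaw error accumulates during
  sustained movement and mixes the body-frame x/y axes; tilt (hence gravity
  removal) is unaffected. The anatomical features tolerate this in
  practice, and tests that isolate frame fidelity inject the generator's
  ground-truth orientation.
* The drift band-pass biases isolated-movement displacement downward (see
  above); all three methods share the bias, so comparisons between them are
  fair, but absolute displacements are conservative.
* Reliability filtering uses all subjects' split-half tables before
  cross-validation; feature selection is therefore not nested, and its
  optimism is shared equally by every method being compared.
* The detector's cross-subject performance on synthetic cohorts is modest
  at high impairment — the most atypical movement patterns are the hardest
  to recognize — so `linear_detected` results depend
  strongly on the detector's operating point.

## A short tour

```{r tour, eval = FALSE}
cohort <- simulate_cohort(n = 17, seed = 1, duration_s = 90)

# segmentation + features + reliability + nested LOSOCV, anatomical method
segtab <- cohort_segments(cohort, method = "anatomical")
result <- assess_cohort(cohort, segtab = segtab, seed = 1)
glance(result)   # rho_bar, output ICC, NRMSE vs FMA-UE
tidy(result)     # Spearman validity against each clinical measure
autoplot(result) # estimates against FMA-UE

# single-sensor variant on annotated straight movements
linear <- assess_cohort(cohort, method = "linear_true", seed = 1)

# how much data does the anatomical method need?
curves <- subsample_experiment(cohort, segtab = segtab, repeats = 5, seed = 1)
plot_subsample_curves(curves)

# does movement type matter?
split <- movement_type_split(cohort, segtab = segtab, seed = 1)
```
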