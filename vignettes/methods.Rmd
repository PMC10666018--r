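---
title: "Models and numerical choices behind msfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices behind msfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfit)
```

`msfit` reimplements the analysis core of a markerless exergame for Pilates
training in multiple sclerosis: a depth sensor emits a 25-joint skeleton at a
nominal 30 Hz, joint trajectories are low-pass filtered, joint-angle
kinematics are compared to a reference gesture template, and a gamified
reward loop plus adherence metrics close the feedback cycle. This vignette
explains the models, the tunable parameters, and the design decisions taken
where the original system left the design open.

## Skeleton model

A frame holds 25 named joints in camera space — x right, y up, z away from
the sensor, meters (the convention of the sensor generation the tool was
built for). Subject distance is defined as the z coordinate of `SpineBase`,
not a Euclidean norm: it is what the capture-range constraint (0.5–4.5 m)
and the placement advice (2–3 m) actually bound, and it is deterministic.
Both intervals are treated as closed. Frame rate is estimated as the median
of reciprocal inter-frame intervals, so isolated dropped frames (double-length
gaps) do not bias the estimate. The on-disk format (header
`#msfit-skeleton v1 fs=<Hz>`, one frame per line) is this package's own
convention; no public format exists for such streams.

## Filtering

Joint trajectories are filtered with an order-3 low-pass Butterworth at 5 Hz
— the stated configuration of the original pipeline; both values are
config-overridable (`order`, `cutoff`) but treated as fixed defaults since
the original optimization procedure is unpublished. The design is the
classical bilinear transform of the analog prototype with cutoff prewarping,
normalized to unit DC gain; coefficients are verified in the test suite
against an independent reference design to 12+ digits.

Filtering is **causal single-pass by default**: the tool's scoring loop is
meant to be realizable online for real-time feedback. A forward–backward
zero-phase variant (`zero_phase = TRUE`) is available for offline analysis;
it squares the magnitude response and removes lag. Initial conditions are
set to the steady state for the first sample, so a signal that starts at
rest produces no start-up transient (a constant passes through exactly).

### Frequency warping

The bilinear transform maps analog to digital frequency through
tan(πf/fs), so the digital magnitude is

  |H(f)| = 1 / sqrt(1 + (tan(πf/fs)/tan(πfc/fs))^(2n)),

which equals the textbook analog form 1/sqrt(1+(f/fc)^(2n)) exactly at
f = fc (both give 1/√2) and to within 0.3% through the passband at
fs = 30 Hz — but **not** near Nyquist: at f = 10 Hz the digital filter's
true gain is 0.0370 while the analog formula predicts 0.1240. This is an
inherent property of every bilinear-designed filter (any standard `butter()`
implementation behaves identically), not an implementation defect. The
module tests therefore verify the measured steady-state attenuation against
the digital analytic magnitude (`butter_gain()`) at 1, 2.5, 5 and 10 Hz,
while the acceptance test that insists on the analog closed form at 10 Hz is
left failing by design — satisfying it would require abandoning the mandated
bilinear design.

### Group-delay compensation

A causal filter delays in-band components by a near-constant group delay
(≈1.74 samples ≈ 58 ms for the default design at 30 Hz). Left
uncompensated, this lag shifts detected repetition boundaries and
misaligns the execution against the template, producing 2–4% of apparent
error on *perfect* input — swamping the 5% correctness budget. The scoring
pipeline therefore shifts the filtered angle series back by the DC group
delay (computed from the coefficients as Σk·b_k/Σb_k − Σk·a_k/Σa_k). This
is still online-realizable: it is the usual fixed-latency labeling of a
real-time filter, not acausal processing.

## Kinematics

Joint angles are 3D interior angles at a (proximal, center, distal) triple,
in [0°, 180°]. Projected planar angles were rejected: without a clinical
protocol the projection plane is arbitrary, whereas the 3D angle is
rotation- and translation-invariant (property-tested under random rigid
transforms). Degenerate frames (zero-length bone) are flagged `NA` rather
than failing the whole series. Velocity and acceleration use central
differences with denominators from actual timestamps, one-sided at the
edges, so dropped frames perturb only their neighborhood.

## Gesture correctness

The original system scored gestures with proprietary machine-learned
detectors; only the metric's interface survives in the record — a
"percentage of error" with a strict 5% correctness threshold. This package
defines the score as **range-of-motion-normalized mean absolute angle
deviation**, weight-averaged over scored joints:
e_j = mean|θ_user − θ_ref|/ROM_j × 100, error = Σ w_j e_j. The choice is
scale-free across joints with different excursions, zero for identical
input, and analytically predictable: a pure amplitude scaling s of a
sinusoidal template yields error (2/π)·|s−1|/2×100, which the tests verify
against dense-quadrature oracles to within 0.5 points.

Time alignment is linear start/end normalization by default; dynamic time
warping is available (`alignment = "dtw"`) for executions at varying speed
within a repetition. Repetitions are delimited at successive minima of the
dominant (highest-weight) joint's angle after smoothing at
min(5, 3/T) Hz — harsh enough to suppress noise-induced spurious minima,
gentle enough to keep the gesture's first harmonics; series start/end act
as boundaries, and segments must last between half and double the template
duration. A flat series (< 1° excursion) contains no repetitions.

The threshold comparison is strict (`error < 5`), and the per-repetition
verdict is primary; session summaries also report the mean.

### Amplitude-scale recovery

For parameter-recovery checks the naive estimator ROM_user/ROM_template is
biased upward by noise extremes (the expected maximum of ~0.5–1° of
filtered angle noise adds several degrees of spurious peak-to-peak range,
4–6% at 5 mm position noise). The default estimator instead regresses the
aligned, centered user trajectory on the centered template shape, with the
template's slope included as a nuisance regressor absorbing residual
sub-frame misalignment (first-order Taylor term). It is unbiased under
additive noise and recovers injected scales within ~2% at 5 mm noise; the
ROM-ratio variant remains available as `method = "rom"`.

## Synthetic motion

The generator is a stated world, not a tuning dial. A fixed-anthropometry
skeleton (1.70 m stature, standard segment proportions, arms along the
body) stands at a configurable distance (default 2.5 m, mid recommended
band). Scored joints are driven with θ(t) = θ₀ − A·cos(2πt/T) — default
θ₀ = 140°, A = 30°, T = 2 s, 5 repetitions at 30 Hz. Two deliberate
choices:

* **Sinusoidal drives** (not minimum-jerk): closed-form error predictions
  make the scorer provable.
* **Cosine phase**: each repetition starts and ends at the rest (minimum
  excursion) posture, so ground-truth repetition boundaries coincide with
  the angle minima the segmenter looks for. The quoted sine form differs
  only by phase and has identical amplitude statistics.

The forward model rotates the subtree distal to each scored joint rigidly
in the plane of the joint, so the generated interior angle equals the
commanded angle to machine precision (verified to ~1e-13). Perturbations:
amplitude scale s (systematic exaggeration/under-execution),
per-repetition phase offsets N(0, σ_phase²), isotropic position noise
N(0, σ_noise²) per joint per frame. 5 mm noise roughly mimics markerless
tracking jitter on stable joints. What the generator does **not** emulate:
MS-specific movement pathology, tracking dropouts/occlusions, soft-tissue
artifacts, systematic sensor bias — so a green pipeline test establishes
algorithmic correctness on idealized motion, not clinical validity.

All generation is seeded and bit-reproducible; the RNG state of the session
is saved and restored around every draw.

## Game engine, sessions, adherence

Calibration requires a ≥5 s window that is simultaneously still (every
joint slower than 0.05 m/s), standing with arms adducted (wrists at or
below hip height + 15 cm, trunk within 15° of vertical), and in capture
range; the stillness and posture tolerances are this package's choices —
only the duration and pose are documented. On success, reference bone
lengths and neutral angles are stored and remain valid across sessions.

Coins accrue per correct repetition (default 1) and buy the next city
(default 50); both are configuration values — the published account reports
total coins collected but never the award schedule, so no default can be
derived from it. Unlocked cities always form a prefix of the itinerary
(property-tested under random operation interleavings), and replaying an
unlocked city reissues its original protocol unchanged. The published
branching travel map is flattened to a linear default itinerary; any
ordered data frame works. Difficulty grows linearly: reps = base + 1 per
city beyond the first, with complexity-gated exercise admission — the
record states difficulty increases but not the schedule.

Missions are predicates over the session log. "Methodic" (the only one
published in the main text) requires ≥2 sessions on each of ≥5 consecutive
calendar days, with days split at local midnight — "twice-daily" is
calendar-day semantics. Completion is monotone. Weeks are ISO-8601
(Mon–Sun) for the ≥150 min/week adherence recommendation; "skipped" means
issued in the protocol but zero scored repetitions.

## Usability statistics

Item statistics are the arithmetic mean and **sample** standard deviation
(n−1), rounded half-up to 2 decimals. Both conventions are inferred, not
stated: the n-denominator SD would give 0.74 where the published playability
row prints 0.78, and only half-up rounding reproduces every printed value.
The packaged 9×8 fixture reproduces all 16 printed statistics exactly, and
the item-mean range is (3.78, 4.33).

## Known limitations

* The gesture-error formula, angle definitions, difficulty schedule, coin
  economy and segmentation rule are principled reconstructions of
  under-specified components, not reverse-engineered originals.
* The scorer is shipped as batch; it is online-realizable (causal filter +
  fixed latency) but no streaming API is exposed.
* DTW alignment is O(nm) exact, fine at gesture lengths (~10² samples);
  long streams should be segmented first.
* Single-person streams only; no depth/color handling, no skeleton fitting,
  no ML gesture detection.
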