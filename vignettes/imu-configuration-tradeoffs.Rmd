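---
title: "Methods: recording-configuration trade-offs for IMU movement classification"
author: "imuconfig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recording-configuration trade-offs for IMU movement classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multi-sensor IMU suits for infants record triaxial acceleration (m/s^2,
8 g range) and angular rate (deg/s, 500 deg/s range) from one sensor per
proximal limb at 52 Hz. A classifier turns these signals into
second-by-second labels on two complementary tracks — posture (7
categories: prone, supine, side left/right, crawl, sitting, standing) and
movement (9 categories: still, proto, elementary, fluent, transition,
rolls and pivots left/right) — and recording-level derivatives: category
distributions and a holistic motor-maturity score (BIMS). The question
this package operationalizes is how much of that analysis survives when
the recording configuration is reduced: fewer sensors, accelerometer-only
modalities, lower sampling frequencies.

Because the clinical recordings behind the original study are not
distributable, the package ships a synthetic-data generator whose
statistical structure mirrors what the analysis assumes, with known
ground truth. Every downstream stage — preprocessing, classification,
agreement statistics, aggregates, the configuration grid — runs end to
end on generated cohorts.

# The synthetic-data generator

## State sequences

Behavior is generated semi-Markov rather than per-frame Markov: bout
durations are drawn explicitly, because the duration structure of real
annotations (almost no sub-second bouts; roughly 10–40% of movement
bouts shorter than 2 s, depending on category) is what makes the
movement track intrinsically harder than the posture track.

* Posture bouts: log-normal, median 12 s (`sdlog` 0.7), truncated at
  2 s. Transitions are occupancy-weighted with a zeroed diagonal.
* Movement bouts: log-normal, median 3.2 s (`sdlog` 0.8), truncated at
  1 s; a posture change cuts the running bout and opens the new one
  with a short "transition" bout (probability 0.6, median 1.8 s).
  Remainders under 1.2 s are absorbed into the previous bout, which is
  why sub-second fragments are essentially absent, as in real data.
* Posture occupancy interpolates linearly with age between a "young"
  profile (62% supine+prone at 4.5 months) and an "old" profile (80%
  crawl+sitting+standing at 16.6 months), and the conditional weight of
  "fluent" grows with age. This monotone occupancy shift is what makes
  the age signal — and hence BIMS — recoverable from distribution
  features.
* Movement categories are drawn conditionally on posture through the
  sensibility constraint (below), so the generator and the aggregation
  stage share one definition of which combinations exist.

## Signals

The accelerometer is a per-limb gravity direction vector for the current
posture (crossfaded over 0.5 s at boundaries via a running mean and
renormalized to 9.81 m/s^2) plus white movement noise whose standard
deviation follows the movement category's energy (0.12 m/s^2 for still
up to 3.0 m/s^2 for fluent). The gyroscope carries a constant 2 deg/s
per-sensor bias in a random direction, white noise scaled by the
category's angular-rate energy (1.5–110 deg/s), and a signed mean rate
on a designated axis during rolls (±45 deg/s about x) and pivots
(±35 deg/s about z), so that left/right variants are separable only
with gyroscope information — this is what makes the gyroscope matter
for the movement track, echoing the real-data finding.

Two placement asymmetries are built in deliberately and documented as
emulation choices, not findings:

* Leg orientation maps leave the lying-side cluster (supine vs side,
  15 degrees) and crawl vs sitting (10 degrees) only marginally
  separated, so a single leg is genuinely ambiguous there; the
  right-leg map is tilted about x so the leg *pair* separates the lying
  cluster better than either leg alone.
* Arm maps collapse prone/crawl and sitting/standing instead, and arms
  receive category-independent extra movement noise plus a per-bout
  energy jitter. Arms therefore disambiguate exactly what legs
  confuse (and vice versa), single-arm placements degrade most, and the
  published placement hierarchy (2A2L > ... > 1A) is recoverable.

## Annotators

Each simulated annotator corrupts the truth independently through
boundary jitter (Gaussian, sd 0.25 s posture / 0.28 s movement) and
whole-segment relabeling from a confusion kernel that favors
perceptually adjacent categories (supine vs side, crawl vs prone,
still vs proto, roll left vs right, ...). Auxiliary carried /
out-of-camera segments cover 6% of the session and are identical across
annotators; frames touching them are excluded from training and
evaluation everywhere.

The relabeling rates (0.018 posture, 0.15 movement) were calibrated
once so that a default cohort reproduces the pairwise multi-annotator
agreement the analysis assumes: Cohen kappa about 0.93 on the posture
track and 0.59 on the movement track (measured 0.937 and 0.587 over
five 20-recording cohorts, ranges 0.934–0.938 and 0.580–0.592). The
movement track's lower agreement emerges mostly from its short bouts
interacting with boundary jitter and the 2.3 s framing — the same
mechanism argued for the real annotations — not from a larger kernel
alone.

What the generator does **not** emulate: biomechanically plausible limb
kinematics, repetitive oscillatory movement spectra, sensor saturation
and temperature drift, annotator-specific systematic biases, or any
video modality. Passing the end-to-end tests therefore shows that the
pipeline recovers the structure this generator encodes — placement
information content, bout statistics, age-linked occupancy — not that
the classifier would reach the same absolute accuracy on clinical
recordings.

# Preprocessing

* **Framing.** 120-sample (2.3 s) windows with 50% overlap (hop 60
  samples, 0.87 frames/s); the frame label is the category with the
  largest overlap with the window, per annotator; the training target is
  the majority vote (ties fall to the first annotator).
* **Sampling-rate reduction** is simulated on the 52 Hz grid so every
  classifier sees identical 120-sample frames: zero-phase sixth-order
  Butterworth anti-alias low-pass at half the decimated rate, integer
  decimation, zero-insertion upsampling, and the same zero-phase
  low-pass (gain-compensated) as reconstruction. The anti-alias pass is
  a deliberate design choice: without it, out-of-band energy aliases
  into the passband and the "sampling rate hardly matters" result
  cannot be emulated cleanly. Nominal 6 and 3 Hz are realized by
  integer factors 8 and 16 (6.5 and 3.25 Hz).
* **Accelerometer split.** Zero-phase eighth-order Butterworth low-pass
  at 0.5 Hz; the high-pass part is the exact subtraction residual, so
  low + high reconstructs the input to machine precision.
* **Gyroscope bias removal** subtracts the per-channel whole-recording
  median — robust because most recording time has near-zero angular
  rate. (The original method is not documented; the median is this
  package's choice.)

All filters are designed as cascaded biquad sections derived from the
Butterworth analog prototype: at 0.5 Hz on a 52 Hz grid a direct-form
order-8 filter is numerically ill-conditioned, and zero-phase
application needs steady-state initial conditions plus reflection
padding to pass constants exactly. The cascade is verified against the
reference design at a moderate cutoff in the test suite.

# The classifier

One input head per modality stream (raw accelerometer: 1 stream; split
accelerometer: low + high = 2; with gyroscope: 3), each a stack of two
strided 1-D convolutions (kernel 5, stride 2) over the 120-sample axis
followed by global average pooling; head embeddings are concatenated and
passed through two dense layers into a per-frame latent vector; a
temporal module of residual blocks applies symmetric dilated
convolutions over the frame axis (kernel 3, dilations 1, 2, 4, 8) and a
linear softmax head closes each track's classifier. The receptive field
is 31 frames ≈ 34.6 s, matching the printed 30-frame figure; the exact
head widths and block counts of the original are not published, so this
architecture is constrained only by the printed latent width (160) and
receptive field. Network, backprop and ADAM are implemented directly in
R matrix operations — the classifier is the object under study, and no
neural-network library is assumed.

Training follows the published protocol: ADAM (beta1 .9, beta2 .999,
eps 1e-8), weighted categorical cross-entropy with inverse-prior class
weights (absent classes get weight 0 with a warning), batches of one
sequence of 100 consecutive frames, augmentation with probability 0.3
each for sensor dropout (never the last remaining sensor), per-sample
dropout (rate 0.3, per sensor), and a random Euler rotation (±15
degrees, applied to every acc and gyro triad), recording-level
cross-validation with a fixed seed, 20% of training recordings held out
for epoch selection by validation kappa.

Two profiles exist. The *reference* profile uses the published
hyperparameters (latent 160, 10 folds, 200 epochs, learning rate 1e-4).
The *small* profile is the tested desk-scale configuration: latent 24,
8-filter heads, 2 folds, 25 epochs, learning rate 3e-3 — chosen once so
that a full 8-placement grid trains on one CPU in minutes; the higher
learning rate simply compensates the much shorter schedule at this
model size. The benchmark problem sizes used throughout the test suite
are a 12-recording cohort of 10-minute sessions for classifier
experiments and a 40-recording, annotation-only cohort for BIMS-age
recovery.

# Agreement statistics

Performance is the Cohen kappa of a compound confusion matrix: one
comparison per (frame, annotator) pair, summed over recordings; in
inter-rater mode annotators are compared in all pair combinations.
Kappa is computed multiclass from observed vs marginal-expected
agreement; on 2x2 tables this reduces exactly to the binary closed form
`2(tp*tn - fn*fp) / ((tp+fp)(fp+tn) + (tp+fn)(fn+tn))`, which the test
suite verifies exhaustively for entries 0–50. Degenerate marginals
(all mass in one row and column) yield `NA`, not a number.

Confidence intervals use the percentile bootstrap (10,000 iterations by
default), always resampling at the recording level and recompounding
per resample. Paired comparisons between configurations matched on the
other attributes use two-tailed paired t tests, preceded by a
one-sample Kolmogorov–Smirnov check of the standardized differences
against the standard normal; the KS test with estimated parameters is
anti-conservative, which is accepted and flagged in the result rather
than corrected, since it only gates a reported caveat. Both published
significance legends appear in the source material; the stricter
(.05, .005, .001) variant is the default and the other is available via
`significance_tier(thresholds=)`.

# Recording-level aggregates

Category distributions are the mean of the carrying-filtered one-hot
matrices along the frame axis. The posture-conditioned movement
representation maps each retained frame to its (posture, movement) pair
over the 27 sensible combinations; the exact membership is not
enumerated in the source material, so the package defines it as the
generator's own constraint set, trimmed to exactly 27 cells and fully
overridable:

* still and transition: all 7 postures (14 cells)
* proto: prone, supine (2)
* elementary: crawl, sitting (2)
* fluent: crawl, sitting, standing (3)
* roll left/right: prone, supine (4)
* pivot left/right: prone (2)

Frames whose predicted pair is non-sensible are dropped and the
distribution renormalized over the sensible mass — how the original
pipeline treated such outputs is not documented; exclusion keeps the
feature vector a proper distribution.

BIMS is the expected age behind a recording's 34-dimensional feature
vector (7 posture + 27 conditioned entries), via exact Gaussian-process
regression with a squared-exponential kernel plus white noise on
standardized features; hyperparameters maximize the marginal likelihood
(Nelder–Mead on log parameters, median-heuristic initialization). The
predicted age is mapped linearly from the training age span onto
[0, 100] and clamped. When BIMS is evaluated, scores are recording-level
cross-validated: a recording's score always comes from a GP fitted
without it, on annotation-derived reference features; the GP needs at
least 10 training recordings spanning at least 6 months.

# The experiment driver

The reference grid is 8 placements x 3 rates (52/26/13 Hz) x 3
modalities = 72 configurations per track; the desk-scale default is 8
placements x 1 rate x 1–2 modalities with the small profile.
Preprocessing is shared within a (modality, rate) group: because every
transform is per-channel, the reduced-placement tensors are exact
channel subsets of the full-placement tensors, and the driver exploits
that instead of re-filtering per placement. Grid runs are resumable
(completed cells are skipped via the results table) and a pure function
of the cohort seed, grid seed and spec. The extreme-decimation report
covers 2A2L and 1A1L with acc+gyro and split-accelerometer modalities
at 13/6/3/2/1 Hz nominal rates.

# Numerical choices and degenerate inputs

* Zero-phase filtering: odd-reflection padding (3 s), per-biquad
  steady-state initial conditions; the upsampling pass instead extends
  the decimated sequence by 20 coarse samples and filters with zero
  initial conditions (steady-state conditions are meaningless for an
  impulse train), and carries the mean around the filter so constants
  pass exactly.
* Frame labeling: per-category overlap tallies; `which.max` breaks
  exact ties toward the earlier category index; majority-vote ties fall
  to annotator 1.
* Training: sequences shorter than 10 frames are merged into the
  previous chunk; folds with a class absent from the training split
  clamp that class weight to 0 with a warning; all-masked sequences are
  skipped.
* Undefined statistics return `NA` markers rather than numbers: kappa
  with degenerate marginals, correlations of zero-variance inputs,
  paired t of identically zero differences, distributions with no
  retained frames.

# Known limitations

* Absolute kappa and correlation levels on synthetic cohorts are not
  comparable to clinical values; only orderings and qualitative effects
  transfer, and the acceptance suite asserts exactly those.
* The desk-scale profile trades optimization stability for speed;
  individual grid cells can swap ranks between adjacent placements on a
  single seed, which is why acceptance uses rank correlation rather
  than per-pair ordering.
* The GP uses a single isotropic length scale on standardized features;
  with 34 correlated distribution features this is adequate for the
  monotone age signal but would underfit richer feature sets.
* `signal::filtfilt`-style edge handling, skeletal kinematics, carrying
  detection itself (the mask is simulated directly), and the original
  iterative annotation-refinement procedure (replaced by majority vote)
  are out of scope.
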