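# imuconfig

Trade-offs between simplifying multi-sensor IMU recordings and the
analyses they can still support, studied end to end on synthetic
infant-movement data with known ground truth.

## The problem

Wearable suits for infants record triaxial accelerometer (m/s², 8 g
range) and gyroscope (deg/s, ±500 deg/s) signals from one IMU per
proximal limb at 52 Hz. A temporal convolutional classifier converts
2.3 s frames (120 samples, 50% overlap) into second-by-second labels on
two annotation tracks — posture (7 categories) and movement (9
categories) — from which recording-level summaries are derived:
carrying-filtered category distributions, the 27 sensible
posture-conditioned movement combinations, and BIMS, a [0, 100] motor
maturity score defined as the Gaussian-process-regressed expectation of
the age most likely to have generated a recording's distribution
features.

The package is for researchers designing wearable movement studies who
need to know what is lost when the recording configuration is reduced
along three axes: sensor placement (the 8 non-empty combinations of 0–2
arm and 0–2 leg sensors, ranked `2A2L > 1A2L > 2A1L > 1A1L > 2L > 1L >
2A > 1A`), sensor modality (accelerometer + gyroscope, raw
accelerometer, or a split into gravity low-pass and movement high-pass
components), and sampling frequency (52/26/13 Hz, with extreme
decimation down to a nominal 1 Hz).

Performance is measured as the Cohen kappa of a compound confusion
matrix (one comparison per frame and annotator, summed over
recordings),

    k = (p_o − p_e) / (1 − p_e),

which on binary collapses equals
`2(tp·tn − fn·fp) / ((tp+fp)(fp+tn) + (tp+fn)(fn+tn))`, with
recording-level percentile-bootstrap CIs and paired t tests between
configurations matched on the other attributes.

Because the original clinical dataset is not distributable, the package
includes a calibrated semi-Markov generator of synthetic cohorts
(age-dependent posture occupancy, log-normal bout durations, per-limb
gravity orientation maps, movement-energy scaling, multi-annotator
corruption with boundary jitter and category confusion, shared
carrying/out-of-camera masks) so that every stage — preprocessing,
training, agreement statistics, aggregates, the configuration grid — is
exercised with known truth. See the methods vignette
(`vignettes/imu-configuration-tradeoffs.Rmd`) for the model and all
design choices.

## Worked example

Generate a small cohort, measure multi-annotator agreement on the
posture track, and compare data rates of the reference and minimal
feasible configurations:

```r
library(imuconfig)

cohort <- generate_cohort(cohort_spec(6, minutes_range = c(8, 12),
                                      seed = 42))
labels <- lapply(cohort$recordings, function(r)
  assign_frame_labels(lapply(r$annotators, `[[`, "posture"),
                      frame_time_grid(duration_s = r$duration_s),
                      r$auxiliary))
cohen_kappa(compound_confusion(labels))

ref <- data_rate(recording_config("2A2L", "acc_gyro", 52))
minimal <- data_rate(recording_config("1A1L", "preproc_acc", 13))
```

Output:

```
inter-rater posture kappa: 0.937
95% CI: [0.896, 0.964]
reference data rate: 1248 numbers/s (5.0 kB/s)
minimal feasible:    78 numbers/s (compression x16)
```

The kappa is the pairwise agreement of the three simulated annotators
after frame-level labeling and carrying-mask exclusion — by calibration
it sits at the human inter-rater level reported for real posture
annotations (≈0.93). The data-rate lines reproduce the configuration
arithmetic: 4 sensors × 6 channels × 52 Hz = 1248 numbers/s (5.0 kB/s
at 32-bit floats) against 2 sensors × 3 channels × 13 Hz = 78
numbers/s, a 16-fold compression.

A full configuration experiment — cross-validated training of the
desk-scale classifier over all 8 placements and both tracks, paired
tests, distribution correlations and BIMS comparisons — runs through
`frame_dataset()`, `train_cross_validated()`, `run_grid()`,
`cohort_summaries()` and `bims_cross_validated()`; the acceptance test
file (`tests/testthat/test-acceptance.R`) is a complete, runnable
script of that workflow.

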