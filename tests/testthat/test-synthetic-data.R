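test_that("state sequences tile the session exactly and respect bout structure", {
  set.seed(21)
  bm <- default_behavior_model()
  tr <- sample_state_sequence(bm, 10, 600)
  for (track in tr) {
    expect_equal(track$start_s[1], 0)
    expect_equal(max(track$end_s), 600)
    if (nrow(track) > 1) {
      expect_equal(track$start_s[-1], track$end_s[-nrow(track)],
                   tolerance = 1e-9)
    }
  }
  # movement bouts are shorter than posture bouts on average
  dp <- tr$posture$end_s - tr$posture$start_s
  dm <- tr$movement$end_s - tr$movement$start_s
  expect_gt(mean(dp), mean(dm))
})

test_that("bout-duration distribution matches the annotated structure", {
  set.seed(22)
  bm <- default_behavior_model()
  dm <- numeric(0); dp <- numeric(0)
  for (i in 1:4) {
    tr <- sample_state_sequence(bm, runif(1, 5, 16), 1800)
    dm <- c(dm, tr$movement$end_s - tr$movement$start_s)
    dp <- c(dp, tr$posture$end_s - tr$posture$start_s)
  }
  frac2 <- mean(dm < 2)
  expect_gte(frac2, 0.10)
  expect_lte(frac2, 0.40)
  # almost no sub-second bouts on either track
  expect_lt(mean(dm < 1), 0.02)
  expect_lt(mean(dp < 1), 0.02)
})

test_that("young infants spend most time lying; occupancy shifts with age", {
  set.seed(23)
  bm <- default_behavior_model()
  occ <- function(age) {
    fr <- replicate(20, {
      tr <- sample_state_sequence(bm, age, 600)
      d <- tr$posture$end_s - tr$posture$start_s
      c(lying = sum(d[tr$posture$category %in% c("supine", "prone")]),
        upright = sum(d[tr$posture$category %in%
                          c("crawl", "sitting", "standing")])) / 600
    })
    rowMeans(fr)
  }
  young <- occ(5); old <- occ(16)
  expect_gt(young["lying"], 0.5)
  expect_gt(old["upright"], young["upright"])
})

test_that("synthesized signals follow gravity, energy and bias semantics", {
  bm <- default_behavior_model(acc_noise_sd = 0, gyro_noise_sd = 0)
  bm$acc_energy[] <- 0; bm$gyro_energy[] <- 0; bm$arm_extra_acc <- 0
  still_prone <- list(
    posture = annotation_track("truth", "posture",
                               segs(0, 120, "prone")),
    movement = annotation_track("truth", "movement",
                                segs(0, 120, "still")))
  set.seed(31)
  rec <- synthesize_imu(still_prone, bm, "degenerate", 8)
  acc <- rec$sensors$LL$acc
  expect_equal(unname(acc[50, ]), 9.81 * c(0, 0, 1), tolerance = 1e-6)
  expect_lt(max(apply(acc, 2, sd)), 1e-9)
  gyro <- rec$sensors$LL$gyro
  expect_lt(max(apply(gyro, 2, sd)), 1e-9)   # bias only
  expect_equal(sqrt(sum(gyro[1, ]^2)), bm$gyro_bias_deg_s,
               tolerance = 1e-6)
})

test_that("movement energy separates fluent from still in the high band", {
  set.seed(32)
  bm <- default_behavior_model()
  tracks <- list(
    posture = annotation_track("truth", "posture",
                               segs(0, 120, "sitting")),
    movement = annotation_track("truth", "movement",
                                segs(0, 60, "still", 60, 120, "fluent")))
  rec <- synthesize_imu(tracks, bm, "x", 10)
  sp <- split_accelerometer(rec$sensors$LL$acc)
  hp_rms <- function(rows) sqrt(mean(sp$high[rows, ]^2))
  fs <- rec$sample_rate
  expect_gt(hp_rms(round(60 * fs):round(118 * fs)),
            2 * hp_rms(round(2 * fs):round(58 * fs)))
  # gravity magnitude during still segments
  mag <- sqrt(rowSums(rec$sensors$LL$acc[1:(60 * fs), ]^2))
  expect_equal(mean(mag), 9.81, tolerance = 0.02 * 9.81)
})

test_that("zero-error annotators agree perfectly; full confusion is chance-level", {
  set.seed(33)
  bm <- default_behavior_model()
  tr <- sample_state_sequence(bm, 9, 900)
  em0 <- default_error_model(posture_confusion = 0,
                             movement_confusion = 0,
                             posture_jitter_s = 0, movement_jitter_s = 0,
                             carrying_fraction = 0)
  ann <- simulate_annotators(tr, em0, 2L)
  ft <- frame_time_grid(duration_s = 900)
  lab <- assign_frame_labels(lapply(ann$annotators, `[[`, "posture"), ft)
  expect_equal(cohen_kappa(compound_confusion(lab)), 1)

  # uniform full confusion drives agreement to chance
  em1 <- default_error_model(posture_confusion = 0.999,
                             posture_jitter_s = 0)
  em1$posture_kernel[] <- 1 / 7
  ks <- replicate(4, {
    tr2 <- sample_state_sequence(bm, 9, 1200)
    ann2 <- simulate_annotators(tr2, em1, 2L)
    lab2 <- assign_frame_labels(lapply(ann2$annotators, `[[`, "posture"),
                                frame_time_grid(duration_s = 1200))
    cohen_kappa(compound_confusion(lab2))
  })
  expect_lt(abs(mean(ks)), 0.1)
})

test_that("cohorts are deterministic given the seed and cover the spec", {
  spec <- cohort_spec(3, minutes_range = c(2, 3), seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$recordings$rec001$recording$sensors$LA$acc,
                   c2$recordings$rec001$recording$sensors$LA$acc)
  expect_identical(c1$recordings$rec002$annotators$A2$movement,
                   c2$recordings$rec002$annotators$A2$movement)
  expect_true(all(c1$manifest$age_months >= 4.5 &
                    c1$manifest$age_months <= 16.6))
  expect_equal(nrow(c1$manifest), 3L)
})

test_that("on-disk cohorts round-trip and refuse accidental overwrite", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(2, minutes_range = c(2, 2), seed = 5)
  coh <- generate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_error(generate_cohort(spec, dir = dir), "overwrite")
  back <- read_recording(file.path(dir, "rec001.csv"))
  orig <- coh$recordings$rec001$recording
  expect_equal(unname(back$sensors$RL$gyro),
               unname(orig$sensors$RL$gyro), tolerance = 1e-6)
  anns <- read_annotations(file.path(dir, "rec001_annotations.tsv"))
  expect_true("truth/posture" %in% names(anns))
  expect_true("A3/movement" %in% names(anns))
})
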