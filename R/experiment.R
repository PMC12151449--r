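#' Enumerate the eight studied sensor placements
#'
#' All combinations of 0-2 arm and 0-2 leg sensors with at least one
#' sensor, in the canonical performance-ranking order (best first):
#' 2A2L, 1A2L, 2A1L, 1A1L, 2L, 1L, 2A, 1A.
#'
#' @return Character vector of 8 placement codes.
#' @export
enumerate_placements <- function() {
  c("2A2L", "1A2L", "2A1L", "1A1L", "2L", "1L", "2A", "1A")
}

#' Raw data rate of a recording configuration
#'
#' Numbers per second transmitted by the hardware: sensors x channels x
#' sampling rate, where a sensor emits 6 channels with the gyroscope
#' enabled (acc+gyro) and 3 otherwise (both accelerometer-only variants
#' measure the same raw accelerometer). Kilobyte = 1000 bytes.
#'
#' @param config A `recording_config`.
#' @param bytes_per_number Bytes per transmitted number (4 for 32-bit
#'   floats).
#' @return `list(numbers_per_s, kB_per_s)`.
#' @export
data_rate <- function(config, bytes_per_number = 4) {
  n_sensors <- config$n_arms + config$n_legs
  if (n_sensors == 0L) stop("data_rate: configuration has no sensors")
  channels <- if (config$modality == "acc_gyro") 6L else 3L
  numbers <- n_sensors * channels * config$sample_rate
  list(numbers_per_s = numbers,
       kB_per_s = numbers * bytes_per_number / 1000)
}

#' Specification of a configuration-grid experiment
#'
#' The reference grid spans 8 placements x 3 sampling rates (52, 26,
#' 13 Hz) x 3 modalities = 72 configurations, each trained for both
#' tracks. The desk-scale default is a reduced grid.
#'
#' @param placements,rates,modalities Grid axes.
#' @param mspec,tc Model and training configuration shared by all cells.
#' @param tracks Tracks to train.
#' @param side Side policy for singleton placements.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(placements = enumerate_placements(),
                      rates = 52, modalities = "acc_gyro",
                      mspec = model_spec("small"),
                      tc = training_config("small"),
                      tracks = c("posture", "movement"),
                      side = "left") {
  stopifnot(all(placements %in% enumerate_placements()),
            all(modalities %in% c("acc_gyro", "raw_acc", "preproc_acc")))
  structure(list(placements = placements, rates = rates,
                 modalities = modalities, mspec = mspec, tc = tc,
                 tracks = tracks, side = side),
            class = "grid_spec")
}

# Restrict a full-placement dataset to a placement subset by selecting
# sensor channel triads (preprocessing is per-channel, so subsetting the
# reference-placement tensors is exactly equivalent to re-running the
# pipeline on the reduced recording).
subset_dataset <- function(dataset, config) {
  all_codes <- sensor_codes()
  keep <- c(if (config$n_arms > 0L)
    (if (config$n_arms == 2L) arm_codes() else
      if (config$side == "left") arm_codes()[1L] else arm_codes()[2L]),
    if (config$n_legs > 0L)
      (if (config$n_legs == 2L) leg_codes() else
        if (config$side == "left") leg_codes()[1L] else leg_codes()[2L]))
  sensor_pos <- match(keep, all_codes)
  rows <- as.vector(vapply(sensor_pos, function(sp)
    (sp - 1L) * 3L + 1:3, integer(3L)))
  lapply(dataset, function(el) {
    el$x <- lapply(el$x, function(a) a[rows, , , drop = FALSE])
    el$frames$frames <- el$x
    el$frames$config <- config
    el
  })
}

#' Run a configuration grid on a synthetic cohort
#'
#' Trains cross-validated classifiers for every (placement, modality,
#' rate) cell and both tracks, and reports out-of-fold Cohen kappa
#' against the human annotations (compound confusion over all
#' annotators), a recording-level bootstrap CI, and kappa against the
#' generator truth. Preprocessing is shared across placements within a
#' (modality, rate) group: the full-placement tensors are computed once
#' and channel-subset per placement. Completed (config, track) pairs
#' present in `done` are skipped, which makes interrupted runs
#' resumable.
#'
#' @param cohort An `imu_cohort` with signals.
#' @param spec A `grid_spec`.
#' @param done Optional previous results table to resume from.
#' @param n_boot Bootstrap iterations for the pooled CI.
#' @param verbose Print one line per trained cell.
#' @return Results data frame (see [write_results_table()]) with one row
#'   per (config, track, fold) plus a pooled row `fold = 0` carrying the
#'   bootstrap CI and truth-referenced kappa.
#' @export
run_grid <- function(cohort, spec = grid_spec(), done = NULL,
                     n_boot = 2000L, verbose = FALSE) {
  rows <- list()
  done_keys <- if (!is.null(done)) {
    unique(paste(done$config_id, done$track))
  } else character(0)
  for (modality in spec$modalities) {
    for (rate in spec$rates) {
      full_cfg <- recording_config("2A2L", modality, rate,
                                   side = spec$side)
      dataset_full <- NULL
      for (placement in spec$placements) {
        cfg <- recording_config(placement, modality, rate,
                                side = spec$side)
        cid <- config_id(cfg)
        todo <- setdiff(paste(cid, spec$tracks), done_keys)
        if (length(todo) == 0L) next
        if (is.null(dataset_full)) {
          dataset_full <- frame_dataset(cohort, full_cfg)
        }
        ds <- if (placement == "2A2L") dataset_full else
          subset_dataset(dataset_full, cfg)
        for (track in spec$tracks) {
          if (paste(cid, track) %in% done_keys) next
          cv <- train_cross_validated(ds, track, spec$mspec, spec$tc)
          res <- grid_cell_rows(ds, cv, cfg, track, n_boot)
          rows[[length(rows) + 1L]] <- res
          if (verbose) {
            message(sprintf("%s %s: kappa=%.3f", cid, track,
                            res$kappa[res$fold == 0]))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(done)) out <- rbind(done, out)
  key <- paste(out$config_id, out$track, out$fold)
  if (anyDuplicated(key)) stop("run_grid: duplicate config ids")
  rownames(out) <- NULL
  out
}

grid_cell_rows <- function(ds, cv, cfg, track, n_boot) {
  truth_lab <- paste0(track, "_truth")
  cms_ann <- mapply(function(el, pr) compound_confusion(el[[track]], pr),
                    ds, cv$predictions, SIMPLIFY = FALSE)
  cms_truth <- mapply(function(el, pr)
    compound_confusion(el[[truth_lab]], pr),
    ds, cv$predictions, SIMPLIFY = FALSE)
  pooled_kappa <- cohen_kappa(Reduce(`+`, cms_ann))
  kappa_truth <- cohen_kappa(Reduce(`+`, cms_truth))
  ci <- bootstrap_ci(cms_ann, function(items)
    cohen_kappa(Reduce(`+`, items)), n_iter = n_boot)
  fold_rows <- lapply(sort(unique(cv$fold)), function(f) {
    ids <- names(cv$fold)[cv$fold == f]
    k <- cohen_kappa(Reduce(`+`, cms_ann[ids]))
    kt <- cohen_kappa(Reduce(`+`, cms_truth[ids]))
    data.frame(config_id = config_id(cfg), placement = cfg$placement,
               modality = cfg$modality, sample_rate_hz = cfg$sample_rate,
               track = track, fold = f, kappa = k, ci_lo = NA_real_,
               ci_hi = NA_real_, kappa_truth = kt)
  })
  rbind(do.call(rbind, fold_rows),
        data.frame(config_id = config_id(cfg), placement = cfg$placement,
                   modality = cfg$modality,
                   sample_rate_hz = cfg$sample_rate, track = track,
                   fold = 0L, kappa = pooled_kappa, ci_lo = ci$lo,
                   ci_hi = ci$hi, kappa_truth = kappa_truth))
}

#' Paired comparisons between matched configurations
#'
#' For one grid attribute (placement, modality or sampling rate), pairs
#' every two attribute values and runs a two-tailed paired t test over
#' the pooled kappas of configurations matched on the other two
#' attributes.
#'
#' @param results Pooled grid results (`fold == 0` rows are used).
#' @param attribute `"placement"`, `"modality"` or `"sample_rate_hz"`.
#' @param track Track to compare.
#' @return Data frame with one row per attribute-value pair: the paired
#'   t statistic, p value, significance tier and number of matched
#'   systems.
#' @export
paired_config_tests <- function(results, attribute = "placement",
                                track = "posture") {
  stopifnot(attribute %in% c("placement", "modality", "sample_rate_hz"))
  res <- results[results$fold == 0 & results$track == track, ]
  others <- setdiff(c("placement", "modality", "sample_rate_hz"),
                    attribute)
  res$match_key <- paste(res[[others[1L]]], res[[others[2L]]])
  vals <- unique(res[[attribute]])
  rows <- list()
  if (length(vals) < 2L) return(NULL)
  for (i in seq_len(length(vals) - 1L)) {
    for (j in seq.int(i + 1L, length(vals))) {
      a <- res[res[[attribute]] == vals[i], ]
      b <- res[res[[attribute]] == vals[j], ]
      keys <- intersect(a$match_key, b$match_key)
      if (length(keys) < 3L) next
      x <- a$kappa[match(keys, a$match_key)]
      y <- b$kappa[match(keys, b$match_key)]
      st <- paired_t(x, y)
      rows[[length(rows) + 1L]] <-
        data.frame(value_a = as.character(vals[i]),
                   value_b = as.character(vals[j]),
                   mean_diff = mean(x - y), t = st$statistic,
                   p = st$p, tier = st$tier, n = st$n)
    }
  }
  do.call(rbind, rows)
}

#' Extreme-decimation experiment
#'
#' Kappa as a function of nominal sampling rate for the four candidate
#' systems (2A2L and 1A1L, each with acc+gyro and pre-processed
#' accelerometer modalities) at rates 13, 6, 3, 2, 1 Hz.
#'
#' @param cohort An `imu_cohort` with signals.
#' @param placements,modalities,rates Grid axes (defaults as studied).
#' @param mspec,tc,done,n_boot As in [run_grid()].
#' @return Results data frame from [run_grid()].
#' @export
extreme_decimation_report <- function(cohort,
                                      placements = c("2A2L", "1A1L"),
                                      modalities = c("acc_gyro",
                                                     "preproc_acc"),
                                      rates = c(13, 6, 3, 2, 1),
                                      mspec = model_spec("small"),
                                      tc = training_config("small"),
                                      done = NULL, n_boot = 2000L) {
  run_grid(cohort, grid_spec(placements = placements, rates = rates,
                             modalities = modalities, mspec = mspec,
                             tc = tc), done = done, n_boot = n_boot)
}
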