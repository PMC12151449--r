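#' Construct and validate a multi-sensor IMU recording
#'
#' A recording holds, for each worn sensor, triaxial accelerometer (m/s^2)
#' and gyroscope (deg/s) signals on a shared uniform time base. Sensors are
#' kept in canonical order (LA, RA, LL, RL). Validation enforces equal
#' lengths across sensors, hardware ranges (8 g accelerometer, +-500 deg/s
#' gyroscope) and a plausible infant age.
#'
#' @param recording_id Character scalar identifier.
#' @param age_months Age of the infant in months, in (0, 36).
#' @param sample_rate Sampling rate in Hz (reference 52).
#' @param sensors Named list (names from [sensor_codes()]); each element a
#'   list with `acc` and `gyro`, both N x 3 numeric matrices.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(recording_id, age_months, sample_rate, sensors) {
  stopifnot(is.character(recording_id), length(recording_id) == 1L,
            is.numeric(age_months), length(age_months) == 1L,
            is.numeric(sample_rate), sample_rate > 0)
  if (age_months <= 0 || age_months >= 36) {
    stop("imu_recording: age_months must lie in (0, 36)")
  }
  if (length(sensors) < 1L || is.null(names(sensors)) ||
      !all(names(sensors) %in% sensor_codes())) {
    stop("imu_recording: sensors must be named with codes ",
         paste(sensor_codes(), collapse = ", "))
  }
  sensors <- sensors[intersect(sensor_codes(), names(sensors))]
  lens <- vapply(sensors, function(s) nrow(s$acc), integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("imu_recording: all sensor blocks must have identical length")
  }
  for (code in names(sensors)) {
    blk <- sensors[[code]]
    if (!is.matrix(blk$acc) || ncol(blk$acc) != 3L ||
        !is.matrix(blk$gyro) || ncol(blk$gyro) != 3L ||
        nrow(blk$gyro) != nrow(blk$acc)) {
      stop("imu_recording: sensor ", code, " must carry N x 3 acc and gyro")
    }
    if (any(abs(blk$acc) > 8 * 9.81)) {
      stop("imu_recording: acc out of the 8 g hardware range in sensor ",
           code)
    }
    if (any(abs(blk$gyro) > 500)) {
      stop("imu_recording: gyro out of the 500 deg/s hardware range in ",
           "sensor ", code)
    }
  }
  structure(list(recording_id = recording_id,
                 age_months = age_months,
                 sample_rate = sample_rate,
                 sensors = sensors),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- recording_length(x)
  cat(sprintf("<imu_recording> %s: %d sensors (%s), %.1f min at %g Hz, age %.1f mo\n",
              x$recording_id, length(x$sensors),
              paste(names(x$sensors), collapse = ","),
              n / x$sample_rate / 60, x$sample_rate, x$age_months))
  invisible(x)
}

#' Number of samples per channel in a recording
#' @param recording An `imu_recording`.
#' @return Integer sample count.
#' @export
recording_length <- function(recording) {
  nrow(recording$sensors[[1L]]$acc)
}

#' @rdname recording_length
#' @export
recording_duration_s <- function(recording) {
  recording_length(recording) / recording$sample_rate
}

#' Construct and validate an interval annotation track
#'
#' @param annotator_id Character scalar.
#' @param track `"posture"`, `"movement"` or `"auxiliary"`.
#' @param segments Data frame with columns `start_s`, `end_s`, `category`.
#'   Segments must be non-overlapping, with `start_s < end_s` and
#'   categories from the track vocabulary; they are sorted by start time.
#' @return An object of class `annotation_track` (a data frame with
#'   attributes `annotator_id` and `track`).
#' @export
annotation_track <- function(annotator_id, track, segments) {
  track <- match.arg(track, c("posture", "movement", "auxiliary"))
  stopifnot(is.character(annotator_id), length(annotator_id) == 1L)
  segments <- as.data.frame(segments)[, c("start_s", "end_s", "category")]
  segments$category <- as.character(segments$category)
  bad <- setdiff(unique(segments$category), track_categories(track))
  if (length(bad) > 0L) {
    stop("annotation_track: unknown ", track, " categories: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(segments) > 0L) {
    if (any(segments$end_s <= segments$start_s)) {
      stop("annotation_track: segments must satisfy start_s < end_s")
    }
    segments <- segments[order(segments$start_s), , drop = FALSE]
    rownames(segments) <- NULL
    if (nrow(segments) > 1L) {
      overlap <- segments$start_s[-1L] <
        segments$end_s[-nrow(segments)] - 1e-9
      if (any(overlap)) {
        stop("annotation_track: overlapping segments within one track")
      }
    }
  }
  structure(segments, annotator_id = annotator_id, track = track,
            class = c("annotation_track", "data.frame"))
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %s/%s: %d segments over [%.1f, %.1f] s\n",
              attr(x, "annotator_id"), attr(x, "track"), nrow(x),
              if (nrow(x)) min(x$start_s) else NA_real_,
              if (nrow(x)) max(x$end_s) else NA_real_))
  invisible(x)
}

#' Recording configuration: placement, modality, sampling rate
#'
#' A studied configuration is a triple of sensor placement (how many arm
#' and leg sensors), sensor modality variant, and nominal sampling rate.
#' Singleton arm or leg placements pick one side via `side` (default left,
#' the configurable convention used throughout).
#'
#' @param placement Placement code such as `"2A2L"`, `"1A1L"`, `"2L"`,
#'   `"1A"`: counts of arm and leg sensors, each in 0..2, at least one
#'   sensor in total.
#' @param modality One of `"acc_gyro"`, `"raw_acc"`, `"preproc_acc"`.
#' @param sample_rate Nominal sampling rate in Hz (52, 26, 13, or the
#'   extreme-decimation set 6, 3, 2, 1).
#' @param side Side used for singleton arm/leg placements, `"left"` or
#'   `"right"`.
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(placement = "2A2L", modality = "acc_gyro",
                             sample_rate = 52, side = "left") {
  modality <- match.arg(modality, c("acc_gyro", "raw_acc", "preproc_acc"))
  side <- match.arg(side, c("left", "right"))
  counts <- parse_placement(placement)
  stopifnot(sample_rate %in% c(52, 26, 13, 6, 3, 2, 1))
  structure(list(placement = placement_code(counts["arms"], counts["legs"]),
                 n_arms = unname(counts["arms"]),
                 n_legs = unname(counts["legs"]),
                 modality = modality,
                 sample_rate = sample_rate,
                 side = side),
            class = "recording_config")
}

parse_placement <- function(placement) {
  m <- regmatches(placement,
                  regexec("^([0-2])A(?:rm[s]?)?([0-2])?L?(?:eg[s]?)?$",
                          placement))[[1L]]
  if (length(m) == 0L) {
    # forms like "2L", "1L" with no arm part
    m2 <- regmatches(placement,
                     regexec("^([0-2])(A|L)(?:rm[s]?|eg[s]?)?$",
                             placement))[[1L]]
    if (length(m2) > 0L) {
      n <- as.integer(m2[2L])
      counts <- if (m2[3L] == "A") c(arms = n, legs = 0L) else
        c(arms = 0L, legs = n)
    } else {
      stop("recording_config: cannot parse placement '", placement, "'")
    }
  } else {
    counts <- c(arms = as.integer(m[2L]),
                legs = if (m[3L] == "") 0L else as.integer(m[3L]))
  }
  if (sum(counts) < 1L) {
    stop("recording_config: at least one sensor is required")
  }
  counts
}

placement_code <- function(n_arms, n_legs) {
  paste0(if (n_arms > 0L) paste0(n_arms, "A") else "",
         if (n_legs > 0L) paste0(n_legs, "L") else "")
}

#' @export
print.recording_config <- function(x, ...) {
  cat(sprintf("<recording_config> %s / %s / %g Hz (side: %s)\n",
              x$placement, x$modality, x$sample_rate, x$side))
  invisible(x)
}

#' Short identifier of a configuration
#' @param config A `recording_config`.
#' @return Character scalar like `"1A1L_preproc_acc_13Hz"`.
#' @export
config_id <- function(config) {
  sprintf("%s_%s_%gHz", config$placement, config$modality,
          config$sample_rate)
}

#' Per-frame one-hot predictions with a validity mask
#'
#' @param frame_times Frame center times in seconds.
#' @param onehot N x K matrix of 0/1, one row per frame; valid rows sum to
#'   one, invalid rows are all zero.
#' @param valid_mask Logical vector, `FALSE` where the frame is excluded
#'   (auxiliary/carrying spans).
#' @return An object of class `frame_predictions`.
#' @export
frame_predictions <- function(frame_times, onehot, valid_mask) {
  stopifnot(nrow(onehot) == length(frame_times),
            length(valid_mask) == length(frame_times))
  rs <- rowSums(onehot)
  if (any(rs[valid_mask] != 1) || any(rs[!valid_mask] != 0)) {
    stop("frame_predictions: valid rows must sum to 1, masked rows to 0")
  }
  structure(list(frame_times = frame_times, onehot = onehot,
                 valid_mask = as.logical(valid_mask)),
            class = "frame_predictions")
}
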