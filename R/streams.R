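#' Restrict a recording to a placement subset
#'
#' Reduced placements are obtained by subsampling sensors from the
#' reference recording. Singleton arm/leg placements take the sensor on
#' the configured side (default left); two-of-a-kind placements take both.
#' Sensor order in the result is canonical (LA, RA, LL, RL).
#'
#' @param recording An `imu_recording`.
#' @param config A `recording_config` (or a placement string, in which
#'   case default modality/rate are assumed).
#' @return An `imu_recording` with the selected sensors only.
#' @export
select_placement <- function(recording, config) {
  if (is.character(config)) config <- recording_config(config)
  pick_side <- function(codes, n) {
    if (n == 0L) return(character(0))
    if (n == 2L) return(codes)
    if (config$side == "left") codes[1L] else codes[2L]
  }
  want <- c(pick_side(arm_codes(), config$n_arms),
            pick_side(leg_codes(), config$n_legs))
  missing_codes <- setdiff(want, names(recording$sensors))
  if (length(missing_codes) > 0L) {
    stop("select_placement: sensors absent from recording: ",
         paste(missing_codes, collapse = ", "))
  }
  recording$sensors <- recording$sensors[intersect(sensor_codes(), want)]
  recording
}

#' Assemble model-input streams for a configuration
#'
#' Applies the configuration's sampling-rate reduction and modality
#' transform and returns the pre-windowing stream stack. Modalities:
#' `raw_acc` gives one stream (raw accelerometer); `preproc_acc` gives two
#' (gravity low-pass, movement high-pass); `acc_gyro` gives three (low,
#' high, bias-removed gyroscope). Channels are concatenated across sensors
#' within each stream, in canonical sensor order.
#'
#' @param recording An `imu_recording`, already restricted to the
#'   configuration's placement (or the full reference recording, in which
#'   case [select_placement()] is applied first).
#' @param config A `recording_config`.
#' @return An object of class `stream_stack`: list with `streams` (named
#'   list of N x (3 * n_sensors) matrices), `sample_rate`, `config`.
#' @export
assemble_streams <- function(recording, config) {
  recording <- select_placement(recording, config)
  fs <- recording$sample_rate
  factor <- decimation_factor(config$sample_rate)
  reduce <- function(mat) {
    if (factor == 1L) mat else reduce_sampling_rate(mat, factor)
  }
  acc <- do.call(cbind, lapply(recording$sensors, function(s) reduce(s$acc)))
  streams <- switch(
    config$modality,
    raw_acc = list(acc = acc),
    preproc_acc = {
      sp <- split_accelerometer(acc, fs)
      list(acc_low = sp$low, acc_high = sp$high)
    },
    acc_gyro = {
      sp <- split_accelerometer(acc, fs)
      gyro <- do.call(cbind, lapply(recording$sensors,
                                    function(s) reduce(s$gyro)))
      list(acc_low = sp$low, acc_high = sp$high,
           gyro = remove_gyro_bias(gyro))
    })
  sensors <- names(recording$sensors)
  streams <- lapply(streams, function(mat) {
    colnames(mat) <- paste(rep(sensors, each = 3L),
                           rep(c("x", "y", "z"), length(sensors)),
                           sep = "_")
    mat
  })
  structure(list(streams = streams, sample_rate = fs,
                 sensors = sensors, config = config),
            class = "stream_stack")
}

#' Segment a stream stack into overlapping analysis frames
#'
#' Frames are 120 samples (2.3 s at 52 Hz) with 50% overlap (hop 60
#' samples); a trailing remainder shorter than one hop is discarded. All
#' configurations carry 120 samples per frame regardless of nominal
#' sampling rate, because reduced rates are realized by filtering on the
#' reference grid.
#'
#' @param streams A `stream_stack` from [assemble_streams()].
#' @return An object of class `frame_tensor`: list with `frames` (named
#'   list of arrays, each `120 x channels x n_frames`), `frame_times`
#'   (window centers, s), `n_frames`.
#' @export
make_frames <- function(streams) {
  stopifnot(inherits(streams, "stream_stack"))
  len <- frame_length_samples()
  hop <- frame_hop_samples()
  n <- nrow(streams$streams[[1L]])
  if (n < len) {
    warning("make_frames: signal shorter than one window; empty tensor")
    return(structure(list(frames = lapply(streams$streams, function(m)
      array(0, c(ncol(m), len, 0L))),
      frame_times = numeric(0), n_frames = 0L,
      config = streams$config), class = "frame_tensor"))
  }
  n_frames <- (n - len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(len), starts, `+`)  # len x n_frames sample indices
  # layout (channels, samples, frames): channel-major for the classifier
  frames <- lapply(streams$streams, function(mat) {
    arr <- array(0, c(ncol(mat), len, n_frames))
    for (ch in seq_len(ncol(mat))) {
      arr[ch, , ] <- mat[idx, ch]
    }
    arr
  })
  frame_times <- (starts + len / 2) / streams$sample_rate
  structure(list(frames = frames, frame_times = frame_times,
                 n_frames = n_frames, config = streams$config),
            class = "frame_tensor")
}

#' Frame center times for a recording of a given length
#'
#' @param n_samples Number of samples on the reference grid (or a
#'   duration in seconds via `duration_s`).
#' @param duration_s Alternative to `n_samples`.
#' @return Numeric vector of frame center times in seconds.
#' @export
frame_time_grid <- function(n_samples = NULL, duration_s = NULL) {
  if (is.null(n_samples)) {
    n_samples <- round(duration_s * reference_sample_rate())
  }
  len <- frame_length_samples()
  hop <- frame_hop_samples()
  if (n_samples < len) return(numeric(0))
  n_frames <- (n_samples - len) %/% hop + 1L
  ((seq_len(n_frames) - 1L) * hop + len / 2) / reference_sample_rate()
}

#' Assign per-frame labels from interval annotation tracks
#'
#' Each frame takes, per annotator, the category with the largest temporal
#' overlap with its 2.3 s window. The training target is the majority
#' vote across annotators (ties resolved by the first annotator). Frames
#' overlapping an auxiliary segment by any amount, and frames not covered
#' by a track, are masked and excluded from training and evaluation.
#'
#' @param tracks List of `annotation_track` objects for one track type
#'   (one per annotator).
#' @param frame_times Frame center times (s) from [make_frames()].
#' @param auxiliary Optional auxiliary `annotation_track`.
#' @param window_s Frame window length in seconds.
#' @return An object of class `frame_labels`: list with `target` (integer
#'   category index per frame, `NA` where masked), `annotators` (frames x
#'   annotators integer matrix), `valid` (logical), `categories`.
#' @export
assign_frame_labels <- function(tracks, frame_times,
                                auxiliary = NULL,
                                window_s = frame_duration_s()) {
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  type <- attr(tracks[[1L]], "track")
  categories <- track_categories(type)
  lo <- frame_times - window_s / 2
  hi <- frame_times + window_s / 2
  lab <- vapply(tracks, function(tr) {
    dominant_category(tr, lo, hi, categories)
  }, integer(length(frame_times)))
  lab <- matrix(lab, nrow = length(frame_times))
  colnames(lab) <- vapply(tracks, attr, "", "annotator_id")
  target <- apply(lab, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_integer_)
    tab <- tabulate(v, length(categories))
    winners <- which(tab == max(tab))
    if (length(winners) == 1L) winners else v[1L]  # tie -> annotator 1
  })
  valid <- !is.na(target)
  if (!is.null(auxiliary) && nrow(auxiliary) > 0L) {
    for (i in seq_len(nrow(auxiliary))) {
      valid <- valid & (hi <= auxiliary$start_s[i] |
                          lo >= auxiliary$end_s[i])
    }
  }
  target[!valid] <- NA_integer_
  structure(list(target = target, annotators = lab, valid = valid,
                 categories = categories, track = type),
            class = "frame_labels")
}

# Integer index of the category with the largest overlap with each
# [lo, hi] window; NA where the track covers none of the window.
dominant_category <- function(track, lo, hi, categories) {
  out <- rep(NA_integer_, length(lo))
  if (nrow(track) == 0L) return(out)
  cat_idx <- match(track$category, categories)
  first <- findInterval(lo, track$end_s, left.open = TRUE) + 1L
  for (f in seq_along(lo)) {
    i <- first[f]
    tally <- numeric(length(categories))
    while (i <= nrow(track) && track$start_s[i] < hi[f]) {
      ov <- min(hi[f], track$end_s[i]) - max(lo[f], track$start_s[i])
      if (ov > 0) tally[cat_idx[i]] <- tally[cat_idx[i]] + ov
      i <- i + 1L
    }
    if (any(tally > 0)) out[f] <- which.max(tally)
  }
  out
}
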