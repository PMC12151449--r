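#' Sample a synthetic posture/movement state sequence
#'
#' Draws gapless posture and movement interval tracks over `[0,
#' duration_s]` from the semi-Markov behavior model: posture bouts with
#' log-normal durations and occupancy-weighted transitions, and movement
#' bouts nested within each posture bout, drawn from the posture's
#' conditional movement distribution (the sensibility constraint). Posture
#' changes cut the running movement bout and, with a configured
#' probability, open the new bout with a short "transition" movement.
#' Remainders shorter than 1.2 s are absorbed into the previous bout so
#' that sub-second fragments are essentially absent, as in real
#' annotations.
#'
#' Uses the R random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param model A `behavior_model`.
#' @param age_months Age in months; shifts occupancy toward upright and
#'   locomotor categories for older ages.
#' @param duration_s Session length in seconds, at least 60.
#' @return `list(posture = annotation_track, movement = annotation_track)`
#'   with annotator id `"truth"`.
#' @export
sample_state_sequence <- function(model, age_months, duration_s) {
  stopifnot(inherits(model, "behavior_model"), duration_s >= 60)
  occ <- posture_occupancy(model, age_months)
  postures <- names(occ)
  if (any(occ < 0) || abs(sum(occ) - 1) > 1e-9) {
    stop("sample_state_sequence: invalid occupancy in behavior model")
  }

  draw_dur <- function(par) {
    max(par$min_s, stats::rlnorm(1L, par$meanlog, par$sdlog))
  }

  # posture bouts
  pd <- model$posture_duration
  cur <- sample(postures, 1L, prob = occ)
  starts <- numeric(0); ends <- numeric(0); cats <- character(0)
  t <- 0
  while (t < duration_s) {
    dur <- draw_dur(pd)
    if (duration_s - (t + dur) < 1.2) dur <- duration_s - t
    starts <- c(starts, t); ends <- c(ends, t + dur); cats <- c(cats, cur)
    t <- t + dur
    if (t < duration_s) {
      w <- occ; w[cur] <- 0
      if (sum(w) <= 0) stop("sample_state_sequence: unreachable state")
      cur <- sample(postures, 1L, prob = w / sum(w))
    }
  }
  posture <- annotation_track("truth", "posture",
                              data.frame(start_s = starts, end_s = ends,
                                         category = cats))

  # movement bouts nested in posture bouts
  md <- model$movement_duration
  te <- model$transition_entry
  ms <- numeric(0); me <- numeric(0); mc <- character(0)
  for (i in seq_len(nrow(posture))) {
    b0 <- posture$start_s[i]; b1 <- posture$end_s[i]
    cond <- movement_conditional(model, posture$category[i], age_months)
    t <- b0
    prev <- NA_character_
    if (i > 1L && stats::runif(1L) < te$prob) {
      dur <- min(draw_dur(te), b1 - t)
      ms <- c(ms, t); me <- c(me, t + dur); mc <- c(mc, "transition")
      t <- t + dur
      prev <- "transition"
    }
    while (t < b1 - 1e-9) {
      w <- cond
      if (!is.na(prev) && prev %in% names(w)) w[prev] <- 0
      if (sum(w) <= 0) w <- cond
      cat_i <- sample(names(w), 1L, prob = w / sum(w))
      dur <- draw_dur(md)
      if (b1 - (t + dur) < 1.2) dur <- b1 - t
      ms <- c(ms, t); me <- c(me, t + dur); mc <- c(mc, cat_i)
      t <- t + dur
      prev <- cat_i
    }
  }
  movement <- annotation_track("truth", "movement",
                               data.frame(start_s = ms, end_s = me,
                                          category = mc))
  list(posture = posture, movement = movement)
}

# Per-sample category index vector for a gapless track on an fs grid.
track_sample_index <- function(track, n, fs, vocabulary) {
  t_s <- (seq_len(n) - 0.5) / fs
  idx <- findInterval(t_s, track$start_s)
  idx[idx < 1L] <- 1L
  match(track$category[idx], vocabulary)
}

#' Synthesize multi-sensor IMU signals from state tracks
#'
#' Produces 52 Hz accelerometer and gyroscope signals for the four limb
#' sensors. The accelerometer is the posture's per-limb gravity direction
#' (crossfaded over 0.5 s at transitions, renormalized to 9.81 m/s^2) plus
#' white movement noise whose amplitude follows the movement category's
#' energy; the gyroscope carries a constant per-sensor bias, white noise
#' scaled by the category's angular-rate energy, and a signed mean rate on
#' a designated axis during rolls and pivots. Arm sensors receive extra
#' category-independent motor noise and a per-bout energy jitter, which
#' makes single-arm configurations the least informative ones by
#' construction.
#'
#' @param tracks `list(posture=, movement=)` from
#'   [sample_state_sequence()].
#' @param model A `behavior_model`.
#' @param recording_id,age_months Metadata for the returned recording.
#' @return An `imu_recording` with all four sensors.
#' @export
synthesize_imu <- function(tracks, model, recording_id = "synthetic",
                           age_months = 10) {
  fs <- reference_sample_rate()
  duration_s <- max(tracks$posture$end_s)
  n <- round(duration_s * fs)
  p_idx <- track_sample_index(tracks$posture, n, fs, posture_categories())
  m_idx <- track_sample_index(tracks$movement, n, fs,
                              movement_categories())
  if (anyNA(p_idx) || anyNA(m_idx)) {
    stop("synthesize_imu: unknown category in track")
  }
  mov_names <- movement_categories()[m_idx]
  k <- max(1L, round(model$crossfade_s * fs))
  smooth_cols <- function(mat) {
    apply(mat, 2L, function(col) {
      padded <- c(rep(col[1L], k), col, rep(col[length(col)], k))
      cs <- cumsum(padded)
      win <- 2L * k + 1L
      (cs[(win):(win + n - 1L)] - c(0, cs[seq_len(n - 1L)])) / win
    })
  }
  acc_sd <- model$acc_noise_sd + model$acc_energy[m_idx]
  gyro_sd <- model$gyro_noise_sd + model$gyro_energy[m_idx]
  rate <- model$gyro_rate_mean[m_idx]
  axis <- model$gyro_rate_axis[m_idx]

  sensors <- list()
  for (code in sensor_codes()) {
    is_arm <- code %in% arm_codes()
    dirs <- model$orientation[[code]][p_idx, , drop = FALSE]
    dirs <- smooth_cols(dirs)
    dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-9)
    sd_i <- acc_sd
    if (is_arm) {
      jit <- stats::runif(nrow(tracks$movement),
                          model$arm_energy_jitter[1L],
                          model$arm_energy_jitter[2L])
      seg <- findInterval((seq_len(n) - 0.5) / fs,
                          tracks$movement$start_s)
      seg[seg < 1L] <- 1L
      sd_i <- sd_i * jit[seg] +
        model$arm_extra_acc * (mov_names != "still")
    }
    acc <- 9.81 * dirs +
      matrix(stats::rnorm(3L * n), n, 3L) * sd_i
    bias_dir <- stats::rnorm(3L)
    bias <- model$gyro_bias_deg_s * bias_dir / sqrt(sum(bias_dir^2))
    gyro <- matrix(stats::rnorm(3L * n), n, 3L) *
      (if (is_arm) 1.5 else 1) * gyro_sd
    for (ax in 1:3) {
      sel <- axis == ax & rate != 0
      if (any(sel)) gyro[sel, ax] <- gyro[sel, ax] + rate[sel]
    }
    gyro <- sweep(gyro, 2L, bias, `+`)
    acc <- pmin(pmax(acc, -8 * 9.81), 8 * 9.81)
    gyro <- pmin(pmax(gyro, -500), 500)
    colnames(acc) <- colnames(gyro) <- c("x", "y", "z")
    sensors[[code]] <- list(acc = acc, gyro = gyro)
  }
  imu_recording(recording_id, age_months, fs, sensors)
}
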