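#' Training-time augmentation of an input sequence
#'
#' Three augmentations are applied independently per sequence, each with
#' its configured probability: sensor dropout (all channels of one
#' randomly chosen sensor zeroed for the whole sequence; never applied
#' when only one sensor is present), sample dropout (each time sample of
#' each sensor zeroed independently at rate 0.3 across that sensor's
#' channels in all streams), and a random rotation (independent per-axis
#' Euler angles, uniform within +-15 degrees, composed and applied to
#' every acc and gyro 3-vector of every sensor).
#'
#' @param xlist Named list of stream arrays `(channels, 120, T)`; within
#'   each stream, channels come in triads per sensor, in canonical sensor
#'   order.
#' @param config A `training_config` (probabilities and rotation bound).
#' @return The augmented list of arrays.
#' @export
augment_sequence <- function(xlist, config) {
  n_ch <- dim(xlist[[1L]])[1L]
  n_sensors <- n_ch %/% 3L
  L <- dim(xlist[[1L]])[2L]
  T <- dim(xlist[[1L]])[3L]
  if (config$p_rotation > 0 && stats::runif(1L) < config$p_rotation) {
    ang <- stats::runif(3L, -config$rotation_deg, config$rotation_deg) *
      pi / 180
    R <- euler_rotation(ang)
    for (s in seq_along(xlist)) {
      for (sensor in seq_len(n_sensors)) {
        rows <- (sensor - 1L) * 3L + 1:3
        blk <- xlist[[s]][rows, , , drop = FALSE]     # (3, L, T)
        dim(blk) <- c(3L, L * T)
        xlist[[s]][rows, , ] <- R %*% blk
      }
    }
  }
  if (config$p_sensor_dropout > 0 && n_sensors > 1L &&
      stats::runif(1L) < config$p_sensor_dropout) {
    sensor <- sample.int(n_sensors, 1L)
    rows <- (sensor - 1L) * 3L + 1:3
    for (s in seq_along(xlist)) xlist[[s]][rows, , ] <- 0
  }
  if (config$p_sample_dropout > 0 &&
      stats::runif(1L) < config$p_sample_dropout) {
    for (sensor in seq_len(n_sensors)) {
      mask <- stats::runif(L * T) < config$sample_dropout_rate
      if (!any(mask)) next
      rows <- (sensor - 1L) * 3L + 1:3
      mask_arr <- array(rep(mask, each = 3L), c(3L, L, T))
      for (s in seq_along(xlist)) {
        blk <- xlist[[s]][rows, , , drop = FALSE]
        dim(blk) <- c(3L, L, T)
        blk[mask_arr] <- 0
        xlist[[s]][rows, , ] <- blk
      }
    }
  }
  xlist
}

euler_rotation <- function(ang) {
  cx <- cos(ang[1L]); sx <- sin(ang[1L])
  cy <- cos(ang[2L]); sy <- sin(ang[2L])
  cz <- cos(ang[3L]); sz <- sin(ang[3L])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3L, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3L, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3L, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
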