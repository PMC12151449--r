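#' Zero-phase Butterworth low-pass filtering
#'
#' Filters are designed as cascaded second-order sections (biquads) derived
#' from the Butterworth analog prototype by bilinear transform. Direct-form
#' coefficient representations of high-order filters become numerically
#' ill-conditioned at the very low normalized cut-offs used here (down to
#' 0.5 Hz on a 52 Hz grid); the cascade is well-conditioned at any cut-off.
#' Zero-phase response is obtained by forward-backward application with
#' odd-reflection edge padding and steady-state initial conditions, so a
#' constant signal passes through exactly.
#'
#' @param order Even filter order (total, across sections).
#' @param w Normalized cut-off frequency, `fc / (fs/2)`, in (0, 1).
#' @return A list of biquad sections, each `list(b, a)` with `a[1] == 1`.
#' @keywords internal
butter_sections <- function(order, w) {
  stopifnot(order %% 2 == 0, order >= 2, w > 0, w < 1)
  k <- tan(pi * w / 2)
  theta <- pi * (2 * seq_len(order %/% 2) + order - 1) / (2 * order)
  lapply(theta, function(th) {
    cc <- -2 * cos(th)  # positive for left-half-plane pole pairs
    a0 <- 1 + cc * k + k^2
    list(b = k^2 * c(1, 2, 1) / a0,
         a = c(1, 2 * (k^2 - 1) / a0, (1 - cc * k + k^2) / a0))
  })
}

# Single forward pass of a biquad cascade with steady-state initial
# conditions pinned to the first sample (removes the step transient).
sections_filter <- function(sections, x) {
  for (s in sections) {
    dc <- sum(s$b) / sum(s$a)
    x <- as.numeric(signal::filter(s$b, s$a, x,
                                   init.x = rep(x[1L], 2L),
                                   init.y = rep(dc * x[1L], 2L)))
  }
  x
}

#' @param x Numeric vector to filter.
#' @param sections Biquad list from [butter_sections()].
#' @rdname butter_sections
#' @keywords internal
zero_phase_filter <- function(x, sections) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop("zero_phase_filter: input contains non-finite samples")
  }
  n <- length(x)
  pad <- min(n - 1L, 156L)  # 3 s at the 52 Hz reference grid
  xp <- if (pad > 0L) {
    c(2 * x[1L] - x[pad:1 + 1L], x, 2 * x[n] - x[n - 1:pad])
  } else {
    x
  }
  y <- sections_filter(sections, xp)
  y <- rev(sections_filter(sections, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Simulate a reduced sampling rate on the original time grid
#'
#' A lower sampling frequency is emulated on the reference grid by
#' anti-alias low-pass filtering, decimating by an integer factor,
#' upsampling back to the reference grid (zero insertion), and a final
#' forward-backward (zero-phase) sixth-order Butterworth low-pass with
#' cut-off at half the decimated sampling frequency, scaled by the
#' factor so that passband gain is unity. The output has the same length
#' as the input, so downstream framing is identical for every rate.
#'
#' @param x Numeric vector (one channel) or a matrix with channels in
#'   columns, on the reference sampling grid.
#' @param factor Positive integer decimation factor (1 = identity).
#' @return Filtered signal with the same shape as `x`.
#' @export
reduce_sampling_rate <- function(x, factor) {
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0 ||
      factor != round(factor)) {
    stop("reduce_sampling_rate: `factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  if (is.matrix(x)) {
    return(apply(x, 2L, reduce_sampling_rate, factor = factor))
  }
  if (factor == 1L) return(x)
  n <- length(x)
  sections <- butter_sections(6L, 1 / factor)  # cut-off 0.5 * fs/factor
  lp <- zero_phase_filter(x, sections)
  dec <- lp[seq.int(1L, n, by = factor)]
  upsample_filter(dec, factor, n, sections)
}

# Zero-insertion upsampling followed by zero-phase low-pass
# reconstruction (gain `factor` compensates the insertion loss). The
# coarse sequence is extended by odd reflection and filtered with zero
# initial conditions so that transients fall entirely in the cropped
# padding (steady-state ICs are meaningless for an impulse train).
upsample_filter <- function(dec, factor, n, sections) {
  m <- length(dec)
  mu <- mean(dec)  # carried around the filter so DC passes exactly
  dec <- dec - mu
  pad <- min(m - 1L, 20L)  # ~e^-16 transient decay at the crop point
  ext <- if (pad > 0L) {
    c(2 * dec[1L] - dec[pad:1 + 1L], dec, 2 * dec[m] - dec[m - 1:pad])
  } else {
    dec
  }
  fine <- numeric(length(ext) * factor)
  fine[(seq_along(ext) - 1L) * factor + 1L] <- ext * factor
  for (s in sections) fine <- as.numeric(signal::filter(s$b, s$a, fine))
  fine <- rev(fine)
  for (s in sections) fine <- as.numeric(signal::filter(s$b, s$a, fine))
  fine <- rev(fine)
  fine[(pad * factor + 1L):(pad * factor + n)] + mu
}

#' Decimation factor realizing a nominal sampling rate
#'
#' Nominal rates are mapped to integer decimation factors of the 52 Hz
#' reference grid: 52, 26, 13 Hz are exact (factors 1, 2, 4); the
#' extreme-decimation rates 6, 3, 2, 1 Hz use factors 8, 16, 26, 52
#' (realized rates 6.5, 3.25, 2 and 1 Hz).
#'
#' @param rate_hz Nominal sampling rate.
#' @return Integer decimation factor.
#' @export
decimation_factor <- function(rate_hz) {
  stopifnot(length(rate_hz) == 1L)
  table <- c(`52` = 1L, `26` = 2L, `13` = 4L, `6` = 8L, `3` = 16L,
             `2` = 26L, `1` = 52L)
  key <- as.character(rate_hz)
  if (!key %in% names(table)) {
    stop("decimation_factor: unsupported nominal rate ", rate_hz)
  }
  unname(table[[key]])
}

#' Split accelerometer signals into gravity and movement components
#'
#' The low-pass component of an accelerometer signal is dominated by
#' gravity and carries the absolute orientation of the sensor; the high-pass
#' residual carries the instantaneous movement. The split uses a zero-phase
#' (forward-backward) eighth-order Butterworth low-pass with 0.5 Hz
#' cut-off; the high-pass part is the exact subtraction residual, so
#' `low + high == input` holds to machine precision.
#'
#' @param acc Numeric vector or matrix (channels in columns), in m/s^2.
#' @param fs Sampling rate in Hz.
#' @return `list(low, high)` with the same shape as `acc`.
#' @export
split_accelerometer <- function(acc, fs = reference_sample_rate()) {
  if (anyNA(acc) || any(!is.finite(acc))) {
    stop("split_accelerometer: input contains non-finite samples")
  }
  sections <- butter_sections(8L, 0.5 / (fs / 2))
  low <- if (is.matrix(acc)) {
    apply(acc, 2L, zero_phase_filter, sections = sections)
  } else {
    zero_phase_filter(acc, sections)
  }
  list(low = low, high = acc - low)
}

#' Remove the constant bias of a gyroscope signal
#'
#' MEMS gyroscopes carry a near-constant per-channel offset. The offset is
#' estimated as the per-channel median over the whole recording, which is
#' robust against movement bouts because most recording time is spent with
#' near-zero angular rate.
#'
#' @param gyro Numeric vector or matrix (channels in columns), deg/s.
#' @return Debiased signal with the same shape.
#' @export
remove_gyro_bias <- function(gyro) {
  if (is.matrix(gyro)) {
    sweep(gyro, 2L, apply(gyro, 2L, stats::median), `-`)
  } else {
    gyro - stats::median(gyro)
  }
}
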