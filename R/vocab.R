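#' Category vocabularies and sensor placements
#'
#' The classification targets are two complementary interval-annotation
#' tracks: a 7-category posture track describing the body configuration and
#' a 9-category movement track describing the ongoing motor activity. A
#' third, auxiliary track marks spans where independent movement cannot be
#' assessed (infant carried, out of camera); such spans are excluded from
#' training and evaluation.
#'
#' @return Character vector of category names, in canonical order.
#' @export
posture_categories <- function() {
  c("prone", "supine", "side_left", "side_right", "crawl", "sitting",
    "standing")
}

#' @rdname posture_categories
#' @export
movement_categories <- function() {
  c("still", "proto", "elementary", "fluent", "transition",
    "roll_left", "roll_right", "pivot_left", "pivot_right")
}

#' @rdname posture_categories
#' @export
auxiliary_categories <- function() {
  c("carried", "out_of_camera")
}

#' @param track One of `"posture"`, `"movement"`, `"auxiliary"`.
#' @rdname posture_categories
#' @export
track_categories <- function(track) {
  switch(match.arg(track, c("posture", "movement", "auxiliary")),
         posture = posture_categories(),
         movement = movement_categories(),
         auxiliary = auxiliary_categories())
}

#' Sensor placement codes
#'
#' The reference wearable carries one IMU per proximal limb. Canonical order
#' is left arm, right arm, left leg, right leg.
#'
#' @return Character vector `c("LA", "RA", "LL", "RL")`.
#' @export
sensor_codes <- function() c("LA", "RA", "LL", "RL")

arm_codes <- function() c("LA", "RA")
leg_codes <- function() c("LL", "RL")

#' Reference recording constants
#'
#' The reference configuration samples triaxial accelerometer (m/s^2,
#' sensitivity 8 g) and gyroscope (deg/s, range +-500 deg/s) at 52 Hz.
#' Analysis frames are 120 samples (2.3 s) with 50% overlap (hop 60
#' samples).
#'
#' @return A scalar constant.
#' @export
reference_sample_rate <- function() 52

#' @rdname reference_sample_rate
#' @export
frame_length_samples <- function() 120L

#' @rdname reference_sample_rate
#' @export
frame_hop_samples <- function() 60L

#' @rdname reference_sample_rate
#' @export
frame_duration_s <- function() frame_length_samples() / reference_sample_rate()

#' @rdname reference_sample_rate
#' @export
frame_hop_s <- function() frame_hop_samples() / reference_sample_rate()

#' @rdname reference_sample_rate
#' @export
frame_rate_hz <- function() reference_sample_rate() / frame_hop_samples()

#' Receptive field of the temporal classifier, in frames and seconds
#'
#' The temporal module looks symmetrically into past and future frames with
#' dilated convolutions (kernel 3, dilations 1, 2, 4, 8), giving a total
#' receptive field of 31 frames, i.e. about 34.6 s at the reference frame
#' hop. `receptive_field_halfwidth()` is the one-sided extent in frames.
#'
#' @param dilations Integer dilation factors of the temporal module.
#' @return Number of frames (integer) or seconds (numeric).
#' @export
receptive_field_frames <- function(dilations = c(1L, 2L, 4L, 8L)) {
  1L + 2L * sum(dilations)
}

#' @rdname receptive_field_frames
#' @export
receptive_field_halfwidth <- function(dilations = c(1L, 2L, 4L, 8L)) {
  sum(dilations)
}

#' @rdname receptive_field_frames
#' @export
receptive_field_s <- function(dilations = c(1L, 2L, 4L, 8L)) {
  receptive_field_halfwidth(dilations) * 2 * frame_hop_s()
}

#' Convert a number of analysis frames to recording hours
#'
#' Frames are produced at one per hop (60 samples at 52 Hz), so `n` frames
#' correspond to `n * 60/52` seconds of recording.
#'
#' @param n_frames Number of frames.
#' @return Hours of recording.
#' @export
frames_to_hours <- function(n_frames) n_frames * frame_hop_s() / 3600

#' Default sensibility matrix of posture x movement combinations
#'
#' Not every movement category is meaningful in every posture: rolls are
#' only possible from lying postures, pivoting only in prone, and fluent
#' locomotor activity only in crawl, sitting or standing. The default
#' matrix marks 27 sensible combinations; "still" and "transition" are
#' sensible in every posture. Rows are postures, columns movements. The
#' matrix is user-overridable wherever it is consumed.
#'
#' @return A 7 x 9 logical matrix with dimnames, 27 entries `TRUE`.
#' @export
sensibility_matrix <- function() {
  p <- posture_categories()
  m <- movement_categories()
  s <- matrix(FALSE, length(p), length(m), dimnames = list(p, m))
  s[, "still"] <- TRUE
  s[, "transition"] <- TRUE
  s[c("prone", "supine"), "proto"] <- TRUE
  s[c("crawl", "sitting"), "elementary"] <- TRUE
  s[c("crawl", "sitting", "standing"), "fluent"] <- TRUE
  s[c("prone", "supine"), c("roll_left", "roll_right")] <- TRUE
  s["prone", c("pivot_left", "pivot_right")] <- TRUE
  s
}

#' Names of the sensible posture x movement combinations
#'
#' @param sensibility Logical posture x movement matrix; defaults to
#'   [sensibility_matrix()].
#' @return Character vector `"<posture>-<movement>"` in row-major order of
#'   the sensibility matrix.
#' @export
sensible_combinations <- function(sensibility = sensibility_matrix()) {
  idx <- which(t(sensibility), arr.ind = TRUE)  # movement-major -> transpose
  paste(rownames(sensibility)[idx[, 2L]], colnames(sensibility)[idx[, 1L]],
        sep = "-")
}
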