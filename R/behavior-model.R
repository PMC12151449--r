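#' Default semi-Markov behavior model for synthetic infant recordings
#'
#' The generator emulates the statistical structure of naturalistic infant
#' play sessions: explicit (semi-Markov) bout durations with log-normal
#' distributions, posture occupancy that shifts with age from lying
#' (supine/prone) toward upright and locomotor postures, movement
#' categories drawn conditionally on posture through the sensibility
#' constraint, and per-limb gravity orientation maps that drive the
#' synthesized accelerometer low-pass component.
#'
#' Two asymmetries are built in deliberately, mirroring how limb placement
#' is expected to behave: leg sensors carry distinct gravity orientations
#' for most postures (only crawl and sitting are close), whereas arm
#' sensors have partially overlapping orientation maps (prone vs crawl,
#' sitting vs standing) plus category-independent motor noise. This is an
#' emulation choice, not a finding.
#'
#' @param acc_noise_sd Baseline accelerometer noise sd (m/s^2).
#' @param gyro_noise_sd Baseline gyroscope noise sd (deg/s).
#' @param gyro_bias_deg_s Magnitude of the constant per-sensor gyro bias.
#' @return An object of class `behavior_model` (a list of parameters).
#' @export
default_behavior_model <- function(acc_noise_sd = 0.25,
                                   gyro_noise_sd = 1.2,
                                   gyro_bias_deg_s = 2) {
  p <- posture_categories()
  m <- movement_categories()

  occ_young <- c(prone = 0.28, supine = 0.34, side_left = 0.08,
                 side_right = 0.08, crawl = 0.10, sitting = 0.09,
                 standing = 0.03)
  occ_old <- c(prone = 0.08, supine = 0.06, side_left = 0.03,
               side_right = 0.03, crawl = 0.22, sitting = 0.30,
               standing = 0.28)

  cond <- matrix(0, length(p), length(m), dimnames = list(p, m))
  cond["prone", ] <- c(0.32, 0.22, 0, 0, 0.06, 0.06, 0.06, 0.14, 0.14)
  cond["supine", ] <- c(0.40, 0.30, 0, 0, 0.08, 0.11, 0.11, 0, 0)
  cond["side_left", ] <- c(0.80, 0, 0, 0, 0.20, 0, 0, 0, 0)
  cond["side_right", ] <- c(0.80, 0, 0, 0, 0.20, 0, 0, 0, 0)
  cond["crawl", ] <- c(0.30, 0, 0.30, 0.30, 0.10, 0, 0, 0, 0)
  cond["sitting", ] <- c(0.35, 0, 0.30, 0.25, 0.10, 0, 0, 0, 0)
  cond["standing", ] <- c(0.45, 0, 0, 0.40, 0.15, 0, 0, 0, 0)
  stopifnot(all(abs(rowSums(cond) - 1) < 1e-9),
            all((cond > 0) <= sensibility_matrix()))

  unit <- function(v) v / sqrt(sum(v^2))
  # legs: lying-side postures and crawl/sitting lie within a few degrees
  # of their neighbors, so a single leg cannot fully resolve them; arms
  # resolve exactly those pairs but collapse prone/crawl and
  # sitting/standing instead
  leg_map <- rbind(prone = c(0, 0, 1),
                   supine = c(0, 0, -1),
                   side_left = unit(c(0, 0.26, -0.966)),
                   side_right = unit(c(0, -0.26, -0.966)),
                   crawl = unit(c(0.985, 0, 0.174)),
                   sitting = c(1, 0, 0),
                   standing = unit(c(0.55, 0, -0.83)))
  arm_map <- rbind(prone = c(0, 0, 1),
                   supine = c(0, 0, -1),
                   side_left = c(0, 1, 0),
                   side_right = c(0, -1, 0),
                   crawl = unit(c(0.17, 0, 0.98)),
                   sitting = c(1, 0, 0),
                   standing = unit(c(0.98, 0, -0.17)))
  rot_z <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L, 3L,
           byrow = TRUE)
  }
  rot_x <- function(deg) {
    th <- deg * pi / 180
    matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3L, 3L,
           byrow = TRUE)
  }
  # the right-leg map is tilted about x so that the leg pair jointly
  # separates the lying-posture cluster better than either leg alone
  orientation <- list(LA = arm_map,
                      RA = arm_map %*% rot_z(12),
                      LL = leg_map,
                      RL = leg_map %*% rot_x(15))
  orientation <- lapply(orientation, function(mm) {
    rownames(mm) <- p
    mm
  })

  acc_energy <- c(still = 0.12, proto = 0.9, elementary = 1.8,
                  fluent = 3.0, transition = 2.2, roll_left = 1.6,
                  roll_right = 1.6, pivot_left = 1.4, pivot_right = 1.4)
  gyro_energy <- c(still = 1.5, proto = 25, elementary = 60, fluent = 110,
                   transition = 80, roll_left = 70, roll_right = 70,
                   pivot_left = 60, pivot_right = 60)
  # Signed mean angular rate (deg/s) on a designated axis: rolls about x,
  # pivots about z; sign encodes direction.
  rate_mean <- c(still = 0, proto = 0, elementary = 0, fluent = 0,
                 transition = 0, roll_left = -45, roll_right = 45,
                 pivot_left = -35, pivot_right = 35)
  rate_axis <- c(still = 1, proto = 1, elementary = 1, fluent = 1,
                 transition = 1, roll_left = 1, roll_right = 1,
                 pivot_left = 3, pivot_right = 3)

  structure(list(
    occupancy_young = occ_young,
    occupancy_old = occ_old,
    age_range = c(4.5, 16.6),
    posture_duration = list(meanlog = log(12), sdlog = 0.7, min_s = 2),
    movement_duration = list(meanlog = log(3.2), sdlog = 0.8, min_s = 1),
    transition_entry = list(prob = 0.6, meanlog = log(1.8), sdlog = 0.4,
                            min_s = 1),
    movement_conditionals = cond,
    fluent_age_scale = c(0.4, 1.2),
    orientation = orientation,
    acc_energy = acc_energy,
    gyro_energy = gyro_energy,
    gyro_rate_mean = rate_mean,
    gyro_rate_axis = rate_axis,
    arm_extra_acc = 0.8,
    arm_energy_jitter = c(0.5, 1.8),
    acc_noise_sd = acc_noise_sd,
    gyro_noise_sd = gyro_noise_sd,
    gyro_bias_deg_s = gyro_bias_deg_s,
    crossfade_s = 0.5
  ), class = "behavior_model")
}

# Linear age interpolation weight in [0, 1] over the model's age range.
age_fraction <- function(model, age_months) {
  r <- model$age_range
  min(1, max(0, (age_months - r[1L]) / (r[2L] - r[1L])))
}

posture_occupancy <- function(model, age_months) {
  a <- age_fraction(model, age_months)
  w <- (1 - a) * model$occupancy_young + a * model$occupancy_old
  w / sum(w)
}

movement_conditional <- function(model, posture, age_months) {
  a <- age_fraction(model, age_months)
  w <- model$movement_conditionals[posture, ]
  sc <- model$fluent_age_scale
  w["fluent"] <- w["fluent"] * (sc[1L] + (sc[2L] - sc[1L]) * a)
  w / sum(w)
}
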