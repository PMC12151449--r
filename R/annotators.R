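#' Default annotator error model
#'
#' Human annotators disagree through two mechanisms emulated here:
#' boundary jitter (segment boundaries shifted by Gaussian noise) and
#' category confusion (a whole segment relabeled from a track-specific
#' confusion kernel that favors perceptually adjacent categories). The
#' default rates are calibrated so that a default synthetic cohort
#' reproduces pairwise inter-rater kappas of about 0.93 (posture) and
#' 0.59 (movement). A fraction of each session is covered by auxiliary
#' (carried / out-of-camera) segments that are identical across
#' annotators and excluded from training and evaluation.
#'
#' @param posture_confusion,movement_confusion Per-segment relabeling
#'   probabilities, in `[0, 1)`.
#' @param posture_jitter_s,movement_jitter_s Boundary jitter sd (s).
#' @param carrying_fraction Fraction of the session covered by auxiliary
#'   segments.
#' @return An object of class `annotator_error_model`.
#' @export
default_error_model <- function(posture_confusion = 0.018,
                                movement_confusion = 0.15,
                                posture_jitter_s = 0.25,
                                movement_jitter_s = 0.28,
                                carrying_fraction = 0.06) {
  stopifnot(posture_confusion >= 0, posture_confusion < 1,
            movement_confusion >= 0, movement_confusion < 1,
            posture_jitter_s >= 0, movement_jitter_s >= 0,
            carrying_fraction >= 0, carrying_fraction < 0.5)
  p <- posture_categories()
  kp <- matrix(0, length(p), length(p), dimnames = list(p, p))
  kp["prone", c("crawl", "side_left", "side_right")] <- c(0.6, 0.2, 0.2)
  kp["supine", c("side_left", "side_right")] <- c(0.5, 0.5)
  kp["side_left", c("supine", "prone")] <- c(0.6, 0.4)
  kp["side_right", c("supine", "prone")] <- c(0.6, 0.4)
  kp["crawl", c("prone", "sitting")] <- c(0.6, 0.4)
  kp["sitting", c("crawl", "standing")] <- c(0.5, 0.5)
  kp["standing", c("sitting")] <- 1
  m <- movement_categories()
  km <- matrix(0, length(m), length(m), dimnames = list(m, m))
  km["still", c("proto", "elementary")] <- c(0.8, 0.2)
  km["proto", c("still", "elementary")] <- c(0.5, 0.5)
  km["elementary", c("proto", "fluent", "still")] <- c(0.4, 0.4, 0.2)
  km["fluent", c("elementary", "transition")] <- c(0.7, 0.3)
  km["transition", c("elementary", "fluent", "proto")] <- c(0.4, 0.3, 0.3)
  km["roll_left", c("roll_right", "transition")] <- c(0.5, 0.5)
  km["roll_right", c("roll_left", "transition")] <- c(0.5, 0.5)
  km["pivot_left", c("pivot_right", "proto")] <- c(0.5, 0.5)
  km["pivot_right", c("pivot_left", "proto")] <- c(0.5, 0.5)
  structure(list(posture_confusion = posture_confusion,
                 movement_confusion = movement_confusion,
                 posture_jitter_s = posture_jitter_s,
                 movement_jitter_s = movement_jitter_s,
                 posture_kernel = kp,
                 movement_kernel = km,
                 carrying_fraction = carrying_fraction,
                 carrying_meanlog = log(25),
                 carrying_sdlog = 0.5),
            class = "annotator_error_model")
}

# Apply boundary jitter + per-segment confusion to one truth track.
corrupt_track <- function(track, annotator_id, jitter_s, confusion,
                          kernel) {
  n <- nrow(track)
  bounds <- c(track$start_s[1L], track$end_s)
  if (n > 1L && jitter_s > 0) {
    inner <- bounds[2:n] + stats::rnorm(n - 1L, 0, jitter_s)
    # keep boundaries ordered with a minimal bout length of 50 ms
    for (i in seq_along(inner)) {
      lo <- if (i == 1L) bounds[1L] else inner[i - 1L]
      inner[i] <- min(max(inner[i], lo + 0.05), bounds[n + 1L] - 0.05 *
                        (n - i))
    }
    bounds <- c(bounds[1L], inner, bounds[n + 1L])
  }
  cats <- track$category
  if (confusion > 0) {
    flip <- stats::runif(n) < confusion
    for (i in which(flip)) {
      w <- kernel[cats[i], ]
      if (sum(w) > 0) {
        cats[i] <- sample(colnames(kernel), 1L, prob = w)
      }
    }
  }
  annotation_track(annotator_id, attr(track, "track"),
                   data.frame(start_s = bounds[-(n + 1L)],
                              end_s = bounds[-1L],
                              category = cats))
}

# Non-overlapping auxiliary (carrying / out-of-camera) segments covering
# roughly `fraction` of [0, duration].
sample_auxiliary <- function(duration_s, error_model) {
  target <- error_model$carrying_fraction * duration_s
  if (target <= 0) {
    return(annotation_track("shared", "auxiliary",
                            data.frame(start_s = numeric(0),
                                       end_s = numeric(0),
                                       category = character(0))))
  }
  durs <- numeric(0)
  while (sum(durs) < target) {
    durs <- c(durs, min(stats::rlnorm(1L, error_model$carrying_meanlog,
                                      error_model$carrying_sdlog),
                        duration_s / 4))
  }
  total <- sum(durs)
  gap_total <- max(duration_s - total, 1)
  gaps <- stats::runif(length(durs) + 1L)
  gaps <- gaps / sum(gaps) * gap_total
  starts <- cumsum(gaps[seq_along(durs)]) +
    c(0, cumsum(durs))[seq_along(durs)]
  cats <- sample(auxiliary_categories(), length(durs), replace = TRUE)
  annotation_track("shared", "auxiliary",
                   data.frame(start_s = starts, end_s = starts + durs,
                              category = cats))
}

#' Simulate independent annotators for a synthetic recording
#'
#' Each annotator receives an independently corrupted copy of the true
#' posture and movement tracks (boundary jitter plus category confusion);
#' one shared auxiliary track of carried / out-of-camera spans is attached
#' to every annotator.
#'
#' Uses the R random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param tracks Truth tracks from [sample_state_sequence()].
#' @param error_model An `annotator_error_model`.
#' @param n_annotators 2 or 3.
#' @return A list with `annotators` (list of per-annotator lists holding
#'   `posture` and `movement` tracks) and `auxiliary` (shared track).
#' @export
simulate_annotators <- function(tracks, error_model = default_error_model(),
                                n_annotators = 3L) {
  stopifnot(inherits(error_model, "annotator_error_model"),
            n_annotators %in% c(2L, 3L))
  duration_s <- max(tracks$posture$end_s)
  aux <- sample_auxiliary(duration_s, error_model)
  annotators <- lapply(seq_len(n_annotators), function(a) {
    id <- paste0("A", a)
    list(posture = corrupt_track(tracks$posture, id,
                                 error_model$posture_jitter_s,
                                 error_model$posture_confusion,
                                 error_model$posture_kernel),
         movement = corrupt_track(tracks$movement, id,
                                  error_model$movement_jitter_s,
                                  error_model$movement_confusion,
                                  error_model$movement_kernel))
  })
  names(annotators) <- paste0("A", seq_len(n_annotators))
  list(annotators = annotators, auxiliary = aux)
}
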