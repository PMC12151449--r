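#' Specification of a synthetic cohort
#'
#' @param n_recordings Number of recordings, at least 1.
#' @param age_range Age range in months (default 4.5 to 16.6).
#' @param minutes_range Session length range in minutes (default 18 to 74;
#'   scale down for desk-scale experiments).
#' @param n_annotators Annotators per recording, 2 or 3.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param behavior A `behavior_model`.
#' @param error_model An `annotator_error_model`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_recordings, age_range = c(4.5, 16.6),
                        minutes_range = c(18, 74), n_annotators = 3L,
                        seed = 1L,
                        behavior = default_behavior_model(),
                        error_model = default_error_model()) {
  stopifnot(n_recordings >= 1L, length(age_range) == 2L,
            age_range[1L] > 0, age_range[2L] < 36,
            diff(age_range) >= 0, minutes_range[1L] >= 1,
            diff(minutes_range) >= 0, n_annotators %in% c(2L, 3L))
  structure(list(n_recordings = as.integer(n_recordings),
                 age_range = age_range,
                 minutes_range = minutes_range,
                 n_annotators = as.integer(n_annotators),
                 seed = as.integer(seed),
                 behavior = behavior,
                 error_model = error_model),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of recordings with annotations
#'
#' Draws ages and session lengths uniformly within the spec's ranges,
#' samples state tracks and annotator corruptions for every recording,
#' and (optionally) synthesizes the IMU signals. With `dir` given, the
#' cohort is also written to disk through the package's readers/writers:
#' one signals CSV and one annotations TSV (truth tracks under annotator
#' `"truth"`, the shared auxiliary track under `"shared"`) per recording,
#' plus a `manifest.csv`.
#'
#' @param spec A `cohort_spec`.
#' @param dir Optional output directory.
#' @param overwrite Refuse to write into an existing non-empty `dir`
#'   unless `TRUE`.
#' @param signals Synthesize IMU signals (set `FALSE` when only tracks
#'   and annotations are needed, e.g. for annotator-agreement studies).
#' @return An object of class `imu_cohort`: a list with `recordings` (one
#'   entry per recording: id, age, duration, truth tracks, annotators,
#'   auxiliary, and the `imu_recording` when `signals = TRUE`) and
#'   `manifest` (data frame).
#' @export
generate_cohort <- function(spec, dir = NULL, overwrite = FALSE,
                            signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
      stop("generate_cohort: output dir exists and is non-empty; ",
           "use overwrite = TRUE")
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  set.seed(spec$seed)
  ages <- stats::runif(spec$n_recordings, spec$age_range[1L],
                       spec$age_range[2L])
  minutes <- stats::runif(spec$n_recordings, spec$minutes_range[1L],
                          spec$minutes_range[2L])
  recordings <- vector("list", spec$n_recordings)
  for (i in seq_len(spec$n_recordings)) {
    rid <- sprintf("rec%03d", i)
    duration_s <- round(minutes[i] * 60)
    truth <- sample_state_sequence(spec$behavior, ages[i], duration_s)
    ann <- simulate_annotators(truth, spec$error_model,
                               spec$n_annotators)
    rec <- if (signals) {
      synthesize_imu(truth, spec$behavior, rid, ages[i])
    }
    recordings[[i]] <- list(recording_id = rid, age_months = ages[i],
                            duration_s = duration_s, truth = truth,
                            annotators = ann$annotators,
                            auxiliary = ann$auxiliary, recording = rec)
  }
  names(recordings) <- vapply(recordings, `[[`, "", "recording_id")
  manifest <- data.frame(
    recording_id = names(recordings),
    age_months = ages,
    duration_s = vapply(recordings, `[[`, 0, "duration_s"),
    n_annotators = spec$n_annotators)
  cohort <- structure(list(recordings = recordings, manifest = manifest,
                           spec = spec),
                      class = "imu_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

write_cohort <- function(cohort, dir) {
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (r in cohort$recordings) {
    if (!is.null(r$recording)) {
      write_recording(r$recording,
                      file.path(dir, paste0(r$recording_id, ".csv")))
    }
    tracks <- list(r$truth$posture, r$truth$movement, r$auxiliary)
    for (a in r$annotators) tracks <- c(tracks, list(a$posture, a$movement))
    write_annotations(tracks,
                      file.path(dir,
                                paste0(r$recording_id, "_annotations.tsv")))
  }
  invisible(dir)
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf("<imu_cohort> %d recordings, ages %.1f-%.1f mo, %s signals\n",
              nrow(x$manifest), min(x$manifest$age_months),
              max(x$manifest$age_months),
              if (is.null(x$recordings[[1L]]$recording)) "without" else
                "with"))
  invisible(x)
}
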