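#' Read and write recordings as long-format CSV
#'
#' Signals are stored in a long format with one row per timestamp per
#' sensor (columns `t_s`, `sensor`, `acc_x..z`, `gyro_x..z`), which
#' tolerates missing sensors naturally. Timestamps are seconds from
#' recording start on a uniform grid; uniformity is enforced on read
#' rather than repaired by resampling.
#'
#' @param path File path.
#' @param recording_id,age_months,sample_rate Metadata for the returned
#'   recording; `sample_rate` defaults to the rate implied by the
#'   timestamps and the others may be carried in a `# key: value` header.
#' @return [read_recording()] returns an `imu_recording`.
#' @export
read_recording <- function(path, recording_id = NULL, age_months = NULL,
                           sample_rate = NULL) {
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  header <- read_kv_header(path)
  if (is.null(recording_id)) {
    recording_id <- header[["recording_id"]] %||%
      sub("\\.csv$", "", basename(path))
  }
  if (is.null(age_months)) {
    age_months <- as.numeric(header[["age_months"]] %||% NA)
  }
  dt <- data.table::fread(path, skip = length(header))
  need <- c("t_s", "sensor", "acc_x", "acc_y", "acc_z",
            "gyro_x", "gyro_y", "gyro_z")
  if (!all(need %in% names(dt))) {
    stop("read_recording: missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  sensors <- list()
  for (code in intersect(sensor_codes(), unique(dt$sensor))) {
    sub <- dt[dt$sensor == code, ]
    sub <- sub[order(sub$t_s), ]
    ts <- sub$t_s
    if (length(ts) >= 2L) {
      dts <- diff(ts)
      fs <- 1 / stats::median(dts)
      if (any(dts > 1.5 / fs)) {
        stop("read_recording: non-uniform timestamps (gap) in sensor ",
             code)
      }
    } else {
      fs <- sample_rate %||% reference_sample_rate()
    }
    acc <- as.matrix(sub[, c("acc_x", "acc_y", "acc_z")])
    gyro <- as.matrix(sub[, c("gyro_x", "gyro_y", "gyro_z")])
    colnames(acc) <- colnames(gyro) <- c("x", "y", "z")
    if (any(abs(acc) > 8 * 9.81)) {
      stop("read_recording: acc values out of range in sensor ", code)
    }
    if (any(abs(gyro) > 500)) {
      stop("read_recording: gyro values out of range in sensor ", code)
    }
    sensors[[code]] <- list(acc = acc, gyro = gyro)
  }
  if (length(sensors) == 0L) stop("read_recording: no sensor rows found")
  if (is.null(sample_rate)) {
    ts <- dt$t_s[dt$sensor == names(sensors)[1L]]
    sample_rate <- if (length(ts) >= 2L) {
      round(1 / stats::median(diff(sort(ts))), 6)
    } else {
      reference_sample_rate()
    }
  }
  if (is.na(age_months)) age_months <- 10  # placeholder when unknown
  imu_recording(recording_id, age_months, sample_rate, sensors)
}

#' @param recording An `imu_recording` to write.
#' @rdname read_recording
#' @export
write_recording <- function(recording, path) {
  n <- recording_length(recording)
  t_s <- (seq_len(n) - 1L) / recording$sample_rate
  blocks <- lapply(names(recording$sensors), function(code) {
    blk <- recording$sensors[[code]]
    data.table::data.table(t_s = t_s, sensor = code,
                           acc_x = blk$acc[, 1L], acc_y = blk$acc[, 2L],
                           acc_z = blk$acc[, 3L],
                           gyro_x = blk$gyro[, 1L], gyro_y = blk$gyro[, 2L],
                           gyro_z = blk$gyro[, 3L])
  })
  dt <- data.table::rbindlist(blocks)
  con <- file(path, "w")
  writeLines(c(sprintf("# recording_id: %s", recording$recording_id),
               sprintf("# age_months: %.6f", recording$age_months)), con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

read_kv_header <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1L]]
    if (length(m) == 3L) out[[trimws(m[2L])]] <- trimws(m[3L])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write annotation tracks as TSV
#'
#' One file holds all (annotator, track) pairs with columns `annotator`,
#' `track`, `category`, `start_s`, `end_s`.
#'
#' @param path File path.
#' @return [read_annotations()] returns a list of `annotation_track`
#'   objects, one per (annotator, track) pair present.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("read_annotations: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("annotator", "track", "category", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("read_annotations: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  keys <- unique(df[, c("annotator", "track")])
  keys <- keys[order(keys$annotator, keys$track), , drop = FALSE]
  tracks <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$annotator == keys$annotator[i] &
                df$track == keys$track[i], , drop = FALSE]
    annotation_track(as.character(keys$annotator[i]),
                     as.character(keys$track[i]),
                     sub[, c("start_s", "end_s", "category")])
  })
  names(tracks) <- paste(keys$annotator, keys$track, sep = "/")
  tracks
}

#' @param tracks List of `annotation_track` objects to write.
#' @rdname read_annotations
#' @export
write_annotations <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    if (nrow(tr) == 0L) return(NULL)
    data.frame(annotator = attr(tr, "annotator_id"),
               track = attr(tr, "track"),
               category = tr$category,
               start_s = tr$start_s, end_s = tr$end_s,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write the grid results table
#'
#' One row per (configuration, track, fold) with the out-of-fold Cohen
#' kappa and its bootstrap confidence bounds. Column order is fixed so the
#' table round-trips losslessly.
#'
#' @param results Data frame with columns `config_id`, `placement`,
#'   `modality`, `sample_rate_hz`, `track`, `fold`, `kappa`, `ci_lo`,
#'   `ci_hi` (extra columns are preserved after the canonical ones).
#' @param path File path.
#' @export
write_results_table <- function(results, path) {
  canonical <- c("config_id", "placement", "modality", "sample_rate_hz",
                 "track", "fold", "kappa", "ci_lo", "ci_hi")
  results <- as.data.frame(results)
  missing_cols <- setdiff(canonical, names(results))
  if (length(missing_cols) > 0L) {
    stop("write_results_table: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(results$config_id, results$track, results$fold)
  if (anyDuplicated(key)) {
    stop("write_results_table: duplicate (config, track, fold) keys")
  }
  extra <- setdiff(names(results), canonical)
  results <- results[, c(canonical, extra), drop = FALSE]
  data.table::fwrite(results, path)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  as.data.frame(data.table::fread(path))
}
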