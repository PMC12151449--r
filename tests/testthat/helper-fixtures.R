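# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except through the package's own writers.

# A tiny two-sensor recording with deterministic content.
tiny_recording <- function(n = 260, sensors = c("LA", "LL"),
                           fs = 52, id = "tiny", age = 8) {
  set.seed(99)
  blocks <- lapply(sensors, function(code) {
    list(acc = cbind(x = rnorm(n, 0, 0.1), y = rnorm(n, 0, 0.1),
                     z = 9.81 + rnorm(n, 0, 0.1)),
         gyro = cbind(x = rnorm(n, 2, 0.5), y = rnorm(n, -1, 0.5),
                      z = rnorm(n, 0, 0.5)))
  })
  names(blocks) <- sensors
  imu_recording(id, age, fs, blocks)
}

# A small annotated cohort with signals, cached per session because
# generation is the expensive part of many tests.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      cohort_spec(4, minutes_range = c(4, 5), seed = 303))
  }
  .fixture_env$cohort
}

# Simple segment table helper.
segs <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(start_s = as.numeric(m[, 1]), end_s = as.numeric(m[, 2]),
             category = m[, 3])
}
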