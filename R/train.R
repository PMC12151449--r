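#' Training protocol configuration
#'
#' Reference protocol: ADAM (learning rate 1e-4, beta1 .9, beta2 .999,
#' epsilon 1e-8), weighted categorical cross-entropy with per-frame
#' weights equal to the inverse prior probability of the target class,
#' batches of one sequence of 100 consecutive frames, 200 epochs,
#' recording-level 10-fold cross-validation with a fixed seed, 20% of the
#' training recordings held out for validation, epoch selection by
#' validation Cohen kappa, and augmentation probabilities of 0.3 each.
#' The desk-scale profile (`scale = "small"`) shortens training (fewer
#' epochs, larger learning rate, fewer folds) so that a full
#' configuration grid runs on one CPU in minutes.
#'
#' @param scale `"small"` or `"reference"`.
#' @param epochs,lr,folds,seed Override individual settings.
#' @param ... Further overrides of the returned fields.
#' @return An object of class `training_config`.
#' @export
training_config <- function(scale = c("small", "reference"),
                            epochs = NULL, lr = NULL, folds = NULL,
                            seed = 1L, ...) {
  scale <- match.arg(scale)
  defaults <- switch(scale,
                     small = list(epochs = 25L, lr = 3e-3, folds = 2L),
                     reference = list(epochs = 200L, lr = 1e-4,
                                      folds = 10L))
  cfg <- list(scale = scale,
              epochs = epochs %||% defaults$epochs,
              lr = lr %||% defaults$lr,
              beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
              folds = folds %||% defaults$folds,
              seed = as.integer(seed),
              batch_frames = 100L,
              val_fraction = 0.2,
              p_sensor_dropout = 0.3,
              p_sample_dropout = 0.3,
              sample_dropout_rate = 0.3,
              p_rotation = 0.3,
              rotation_deg = 15)
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  structure(cfg, class = "training_config")
}

#' Build the model-ready dataset for a cohort and configuration
#'
#' Applies the configuration transforms (placement, modality, sampling
#' rate), frames the streams, and attaches frame labels: per-annotator
#' labels, the majority-vote training target, truth labels, and the
#' auxiliary mask.
#'
#' @param cohort An `imu_cohort` generated with signals.
#' @param config A `recording_config`.
#' @return List with one element per recording: `x` (stream arrays),
#'   `frame_times`, and `frame_labels` objects `posture`, `movement`,
#'   `posture_truth`, `movement_truth`.
#' @export
frame_dataset <- function(cohort, config) {
  lapply(cohort$recordings, function(r) {
    if (is.null(r$recording)) {
      stop("frame_dataset: cohort was generated without signals")
    }
    frames <- make_frames(assemble_streams(r$recording, config))
    ft <- frames$frame_times
    list(recording_id = r$recording_id,
         age_months = r$age_months,
         x = frames$frames,
         frame_times = ft,
         frames = frames,
         posture = assign_frame_labels(
           lapply(r$annotators, `[[`, "posture"), ft, r$auxiliary),
         movement = assign_frame_labels(
           lapply(r$annotators, `[[`, "movement"), ft, r$auxiliary),
         posture_truth = assign_frame_labels(
           list(r$truth$posture), ft, r$auxiliary),
         movement_truth = assign_frame_labels(
           list(r$truth$movement), ft, r$auxiliary))
  })
}

# Inverse-prior class weights on the training targets; classes absent
# from the fold get weight 0 with a warning.
class_weights_from <- function(targets, n_classes) {
  counts <- tabulate(targets[!is.na(targets)], n_classes)
  w <- numeric(n_classes)
  present <- counts > 0
  if (!all(present)) {
    warning("class weights: ", sum(!present),
            " class(es) absent from the training fold; weight clamped to 0")
  }
  w[present] <- sum(counts) / counts[present]
  w[present] <- w[present] / mean(w[present])
  w
}

# Consecutive chunks of at most `len` frames; tails shorter than 10
# frames are merged into the previous chunk.
sequence_chunks <- function(T, len) {
  if (T <= len) return(list(seq_len(T)))
  starts <- seq.int(1L, T, by = len)
  chunks <- lapply(starts, function(s) seq.int(s, min(s + len - 1L, T)))
  last <- length(chunks)
  if (length(chunks[[last]]) < 10L && last > 1L) {
    chunks[[last - 1L]] <- c(chunks[[last - 1L]], chunks[[last]])
    chunks <- chunks[-last]
  }
  chunks
}

slice_frames <- function(xlist, idx) {
  lapply(xlist, function(a) a[, , idx, drop = FALSE])
}

# Train one classifier on the given recordings; model selection by
# validation kappa. `labels_of` extracts the frame_labels object of the
# trained track from a dataset element.
train_classifier <- function(dataset, train_ids, val_ids, track,
                             mspec, tc, init_seed = 1L) {
  n_classes <- length(dataset[[train_ids[1L]]][[track]]$categories)
  stream_channels <- vapply(dataset[[train_ids[1L]]]$x,
                            function(a) dim(a)[1L], 0L)
  model <- build_model(mspec, stream_channels, n_classes,
                       seed = init_seed)
  targets <- unlist(lapply(train_ids, function(i)
    dataset[[i]][[track]]$target))
  cw <- class_weights_from(targets, n_classes)
  chunks <- list()
  for (i in train_ids) {
    for (ch in sequence_chunks(length(dataset[[i]]$frame_times),
                               tc$batch_frames)) {
      chunks[[length(chunks) + 1L]] <- list(rec = i, idx = ch)
    }
  }
  state <- adam_state(model$params)
  best <- list(kappa = -Inf, params = model$params)
  log <- numeric(tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    for (ci in sample(length(chunks))) {
      ch <- chunks[[ci]]
      el <- dataset[[ch$rec]]
      x <- slice_frames(el$x, ch$idx)
      x <- augment_sequence(x, tc)
      lab <- el[[track]]
      y <- lab$target[ch$idx]
      valid <- lab$valid[ch$idx]
      fw <- nn_forward(model, x, keep_cache = TRUE)
      ce <- weighted_ce(fw$logits, y, valid, cw)
      if (is.na(ce$loss)) next
      g <- nn_backward(model, x, fw, ce$dlogits)
      upd <- adam_step(model$params, g, state, tc$lr, tc$beta1,
                       tc$beta2, tc$eps)
      model$params <- upd$params
      state <- upd$state
    }
    k <- validation_kappa(model, dataset, val_ids, track)
    log[epoch] <- k
    if (!is.na(k) && k > best$kappa) {
      best <- list(kappa = k, params = model$params)
    }
  }
  model$params <- best$params
  list(model = model, val_kappa = best$kappa, epoch_log = log,
       class_weights = cw)
}

validation_kappa <- function(model, dataset, ids, track) {
  cms <- lapply(ids, function(i) {
    el <- dataset[[i]]
    logits <- nn_forward(model, el$x)$logits
    pred <- max.col(logits, ties.method = "first")
    lab <- el[[track]]
    ok <- lab$valid & !is.na(lab$target)
    pair_confusion(lab$target, pred, ok, length(lab$categories))
  })
  cm <- Reduce(`+`, cms)
  if (sum(cm) == 0) return(NA_real_)
  cohen_kappa(cm)
}

#' Recording-level cross-validated training
#'
#' Partitions recordings into folds with a fixed seed, trains one
#' classifier per fold on the remaining recordings (with a held-out
#' validation fraction for epoch selection by Cohen kappa), and predicts
#' every recording exactly once with the model that never saw it.
#'
#' @param dataset From [frame_dataset()].
#' @param track `"posture"` or `"movement"`.
#' @param mspec A `model_spec`.
#' @param tc A `training_config`.
#' @return List with `predictions` (named list of `frame_predictions`),
#'   `fold` (fold index per recording), `models` (per fold), and
#'   `val_kappa` (per fold).
#' @export
train_cross_validated <- function(dataset, track = "posture",
                                  mspec = model_spec("small"),
                                  tc = training_config("small")) {
  n <- length(dataset)
  folds <- tc$folds
  if (n < folds) stop("train_cross_validated: fewer recordings than folds")
  set.seed(tc$seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  names(fold) <- names(dataset)
  predictions <- vector("list", n)
  names(predictions) <- names(dataset)
  models <- vector("list", folds)
  val_kappas <- numeric(folds)
  for (f in seq_len(folds)) {
    test_ids <- which(fold == f)
    rest <- which(fold != f)
    n_val <- max(1L, round(tc$val_fraction * length(rest)))
    val_ids <- rest[sample.int(length(rest), n_val)]
    train_ids <- setdiff(rest, val_ids)
    fit <- train_classifier(dataset, train_ids, val_ids, track, mspec,
                            tc, init_seed = tc$seed + f)
    models[[f]] <- fit$model
    val_kappas[f] <- fit$val_kappa
    for (i in test_ids) {
      el <- dataset[[i]]
      predictions[[i]] <- predict_frames(fit$model, el$frames,
                                         el[[track]]$valid)
    }
  }
  list(predictions = predictions, fold = fold, models = models,
       val_kappa = val_kappas, track = track)
}
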