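# Small deterministic inputs for architecture-level checks.
toy_streams <- function(T = 40, channels = c(acc_low = 6L, gyro = 6L),
                        seed = 14) {
  set.seed(seed)
  xl <- lapply(channels, function(C) array(rnorm(C * 120 * T),
                                           c(C, 120, T)))
  names(xl) <- names(channels)
  xl
}

test_that("the model has one input head per stream and a softmax simplex", {
  ms <- model_spec("small")
  m3 <- build_model(ms, c(acc_low = 12L, acc_high = 12L, gyro = 12L), 7L)
  expect_length(grep("^Wh1_", names(m3$params)), 3L)
  m1 <- build_model(ms, c(acc = 6L), 7L)
  expect_length(grep("^Wh1_", names(m1$params)), 1L)
  xl <- toy_streams(10, c(acc = 6L))
  p <- imuconfig:::softmax_rows(imuconfig:::nn_forward(m1, xl)$logits)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("reference scale realizes the printed latent width and receptive field", {
  ms <- model_spec("reference")
  expect_equal(ms$latent, 160L)
  expect_equal(receptive_field_frames(ms$dilations), 31L)
  expect_equal(receptive_field_s(ms$dilations), 30 * 60 / 52,
               tolerance = 1e-9)
})

test_that("predictions are deterministic, one-hot, and padding-invariant", {
  ms <- model_spec("small", head_filters = 4L, latent = 8L)
  mod <- build_model(ms, c(acc = 6L), 7L, seed = 3)
  xl <- toy_streams(50, c(acc = 6L))
  ft <- structure(list(frames = xl, frame_times = seq_len(50),
                       n_frames = 50L), class = "frame_tensor")
  p1 <- predict_frames(mod, ft)
  p2 <- predict_frames(mod, ft)
  expect_identical(p1$onehot, p2$onehot)
  expect_true(all(rowSums(p1$onehot) == 1))
  # appending frames beyond the receptive field leaves early frames alone
  halfwidth <- receptive_field_halfwidth(ms$dilations)
  xl_pad <- lapply(xl, function(a) {
    pad <- array(rnorm(length(a[, , 1:10])), c(dim(a)[1:2], 10))
    arr <- array(0, dim(a) + c(0, 0, 10))
    arr[, , 1:50] <- a; arr[, , 51:60] <- pad
    arr
  })
  ft_pad <- structure(list(frames = xl_pad, frame_times = seq_len(60),
                           n_frames = 60L), class = "frame_tensor")
  p3 <- predict_frames(mod, ft_pad)
  unaffected <- seq_len(50 - halfwidth)
  expect_identical(p3$onehot[unaffected, ], p1$onehot[unaffected, ])
})

test_that("temporal receptive field is local: |i - j| <= 15", {
  ms <- model_spec("small", head_filters = 4L, latent = 8L)
  mod <- build_model(ms, c(acc = 3L), 5L, seed = 6)
  xl <- toy_streams(70, c(acc = 3L), seed = 15)
  base <- imuconfig:::nn_forward(mod, xl)$logits
  j <- 35L
  xl2 <- xl
  xl2$acc[, , j] <- xl2$acc[, , j] + 5
  pert <- imuconfig:::nn_forward(mod, xl2)$logits
  changed <- which(rowSums(abs(pert - base)) > 1e-9)
  expect_true(all(abs(changed - j) <= 15))
  expect_true(j %in% changed)
})

test_that("augmentations preserve the advertised invariants", {
  tc0 <- training_config("small", p_sensor_dropout = 0,
                         p_sample_dropout = 0, p_rotation = 0)
  xl <- toy_streams(20, c(acc_low = 6L, acc_high = 6L))
  set.seed(2)
  expect_identical(augment_sequence(xl, tc0), xl)
  # rotation-only: vector norms preserved per sample
  tcr <- training_config("small", p_sensor_dropout = 0,
                         p_sample_dropout = 0, p_rotation = 1)
  set.seed(3)
  out <- augment_sequence(xl, tcr)
  norms_in <- sqrt(colSums(xl$acc_low[1:3, , 5]^2))
  norms_out <- sqrt(colSums(out$acc_low[1:3, , 5]^2))
  expect_equal(norms_out, norms_in, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(out$acc_low, xl$acc_low)))
  # sensor dropout never removes the only sensor
  tcd <- training_config("small", p_sensor_dropout = 1,
                         p_sample_dropout = 0, p_rotation = 0)
  one <- toy_streams(10, c(acc = 3L))
  set.seed(4)
  expect_identical(augment_sequence(one, tcd), one)
  two <- toy_streams(10, c(acc = 6L))
  set.seed(5)
  dropped <- augment_sequence(two, tcd)
  zeroed <- vapply(1:2, function(s)
    all(dropped$acc[(s - 1) * 3 + 1:3, , ] == 0), TRUE)
  expect_equal(sum(zeroed), 1L)
})

# A miniature two-class dataset in the frame_dataset layout: class B is
# rare (about 10%) and separated only by a mean shift, so unweighted
# training collapses onto the majority class.
toy_dataset <- function(n_rec = 4, T = 120, p_minority = 0.1,
                        shift = 1.2, seed = 8) {
  set.seed(seed)
  lapply(seq_len(n_rec), function(i) {
    y <- 1L + (runif(T) < p_minority)
    x <- array(rnorm(3 * 120 * T), c(3, 120, T))
    x[, , y == 2L] <- x[, , y == 2L] + shift
    lab <- structure(list(target = y,
                          annotators = matrix(y, ncol = 1),
                          valid = rep(TRUE, T),
                          categories = c("common", "rare"),
                          track = "posture"),
                     class = "frame_labels")
    list(recording_id = paste0("r", i), age_months = 10,
         x = list(acc = x), frame_times = seq_len(T),
         frames = structure(list(frames = list(acc = x),
                                 frame_times = seq_len(T),
                                 n_frames = T),
                            class = "frame_tensor"),
         posture = lab, posture_truth = lab)
  })
}

test_that("inverse-prior weighting recovers minority-class recall", {
  # weak separation: the class shift is well below the frame-pooled
  # noise floor times the 9:1 prior odds, so unweighted training
  # collapses onto the majority class
  ds <- toy_dataset(shift = 0.2, T = 150)
  names(ds) <- vapply(ds, `[[`, "", "recording_id")
  ms <- model_spec("small", head_filters = 4L, latent = 8L,
                   dilations = c(1L, 2L))
  tc <- training_config("small", epochs = 15L, folds = 2L, seed = 2,
                        p_sensor_dropout = 0, p_sample_dropout = 0,
                        p_rotation = 0)
  recall_rare <- function(weighted) {
    if (!weighted) {
      # neutralize the inverse-prior weighting via uniform priors
      local_cw <- function(targets, n_classes) rep(1, n_classes)
      fit <- with_mocked_bindings(
        imuconfig:::train_classifier(ds, 1:3, 4, "posture", ms, tc,
                                     init_seed = 7),
        class_weights_from = local_cw,
        .package = "imuconfig")
    } else {
      fit <- imuconfig:::train_classifier(ds, 1:3, 4, "posture", ms, tc,
                                          init_seed = 7)
    }
    el <- ds[[4]]
    pred <- max.col(imuconfig:::nn_forward(fit$model, el$x)$logits)
    rare <- el$posture$target == 2L
    mean(pred[rare] == 2L)
  }
  rw <- recall_rare(TRUE)
  ru <- recall_rare(FALSE)
  expect_gte(rw, 0.7)
  expect_gt(rw, ru)
})

test_that("shuffled labels give chance-level kappa on a learnable task", {
  ds <- toy_dataset(n_rec = 4, T = 400, p_minority = 0.4, shift = 1,
                    seed = 12)
  names(ds) <- vapply(ds, `[[`, "", "recording_id")
  ms <- model_spec("small", head_filters = 4L, latent = 8L,
                   dilations = c(1L, 2L))
  tc <- training_config("small", epochs = 10L, folds = 2L, seed = 3,
                        p_sensor_dropout = 0, p_sample_dropout = 0,
                        p_rotation = 0)
  holdout_kappa <- function(ds) {
    fit <- imuconfig:::train_classifier(ds, 1:2, 3, "posture", ms, tc,
                                        init_seed = 5)
    el <- ds[[4]]
    pred <- max.col(imuconfig:::nn_forward(fit$model, el$x)$logits)
    cohen_kappa(imuconfig:::pair_confusion(el$posture$target, pred,
                                           el$posture$valid, 2L))
  }
  expect_gt(holdout_kappa(ds), 0.5)
  set.seed(99)
  ds_shuf <- lapply(ds, function(el) {
    perm <- sample(length(el$posture$target))
    el$posture$target <- el$posture$target[perm]
    el$posture$annotators <- el$posture$annotators[perm, , drop = FALSE]
    el
  })
  expect_lt(abs(holdout_kappa(ds_shuf)), 0.1)
})

test_that("cross-validation partitions recordings and is seed-reproducible", {
  ds <- toy_dataset(n_rec = 4, seed = 20)
  names(ds) <- vapply(ds, `[[`, "", "recording_id")
  ms <- model_spec("small", head_filters = 4L, latent = 8L,
                   dilations = c(1L, 2L))
  tc <- training_config("small", epochs = 2L, folds = 2L, seed = 4)
  cv1 <- train_cross_validated(ds, "posture", ms, tc)
  cv2 <- train_cross_validated(ds, "posture", ms, tc)
  expect_identical(cv1$fold, cv2$fold)
  expect_equal(sort(unname(cv1$fold)), c(1L, 1L, 2L, 2L))
  expect_identical(cv1$predictions$r1$onehot, cv2$predictions$r1$onehot)
  expect_null(cv1$predictions[["nonexistent"]])
  expect_true(all(!vapply(cv1$predictions, is.null, TRUE)))
})
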