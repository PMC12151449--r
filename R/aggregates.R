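#' Recording-level category distribution
#'
#' Mean of the carrying-filtered one-hot matrix along the frame axis:
#' the fraction of retained frames spent in each category.
#'
#' @param onehot N x K one-hot matrix (e.g. from `frame_predictions`).
#' @param mask Logical vector of frames to retain (carrying filter).
#' @return Length-K distribution summing to 1, or all-`NA` when no frame
#'   is retained (undefined).
#' @export
category_distribution <- function(onehot, mask = rep(TRUE, nrow(onehot))) {
  stopifnot(length(mask) == nrow(onehot))
  keep <- mask & rowSums(onehot) > 0
  if (!any(keep)) return(rep(NA_real_, ncol(onehot)))
  colSums(onehot[keep, , drop = FALSE]) / sum(keep)
}

#' Posture-conditioned movement distribution
#'
#' Maps every retained frame to its (posture, movement) pair and returns
#' the distribution over the sensible combinations; frames whose pair is
#' not sensible are dropped and the distribution renormalized over the
#' sensible mass.
#'
#' @param posture_onehot,movement_onehot Aligned one-hot matrices.
#' @param mask Logical retention vector.
#' @param sensibility Logical posture x movement matrix
#'   ([sensibility_matrix()] by default, 27 sensible cells).
#' @return Named distribution over the sensible combinations (length 27
#'   with the default matrix), or all-`NA` when no retained frame is
#'   sensible.
#' @export
conditioned_distribution <- function(posture_onehot, movement_onehot,
                                     mask = rep(TRUE,
                                                nrow(posture_onehot)),
                                     sensibility = sensibility_matrix()) {
  stopifnot(nrow(posture_onehot) == nrow(movement_onehot),
            length(mask) == nrow(posture_onehot))
  combos <- sensible_combinations(sensibility)
  keep <- mask & rowSums(posture_onehot) > 0 &
    rowSums(movement_onehot) > 0
  out <- stats::setNames(rep(NA_real_, length(combos)), combos)
  if (!any(keep)) return(out)
  p_idx <- max.col(posture_onehot[keep, , drop = FALSE],
                   ties.method = "first")
  m_idx <- max.col(movement_onehot[keep, , drop = FALSE],
                   ties.method = "first")
  sensible <- sensibility[cbind(p_idx, m_idx)]
  if (!any(sensible)) return(out)
  name <- paste(rownames(sensibility)[p_idx[sensible]],
                colnames(sensibility)[m_idx[sensible]], sep = "-")
  counts <- table(factor(name, levels = combos))
  stats::setNames(as.numeric(counts) / sum(counts), combos)
}

#' Recording summary feature vector
#'
#' Concatenates the posture distribution (7) and the posture-conditioned
#' movement distribution (27) into the 34-dimensional feature vector used
#' for holistic scoring.
#'
#' @param posture_onehot,movement_onehot,mask,sensibility As in
#'   [conditioned_distribution()].
#' @return Named numeric vector of length 34 (with the default
#'   sensibility matrix).
#' @export
summary_features <- function(posture_onehot, movement_onehot,
                             mask = rep(TRUE, nrow(posture_onehot)),
                             sensibility = sensibility_matrix()) {
  pd <- category_distribution(posture_onehot, mask)
  names(pd) <- posture_categories()
  cd <- conditioned_distribution(posture_onehot, movement_onehot, mask,
                                 sensibility)
  c(pd, cd)
}

#' One-hot matrix from frame labels
#'
#' @param labels A `frame_labels` object; the majority-vote target is
#'   one-hot coded, masked frames give all-zero rows.
#' @return N x K matrix of 0/1.
#' @export
labels_onehot <- function(labels) {
  k <- length(labels$categories)
  oh <- matrix(0L, length(labels$target), k,
               dimnames = list(NULL, labels$categories))
  sel <- which(labels$valid & !is.na(labels$target))
  oh[cbind(sel, labels$target[sel])] <- 1L
  oh
}

#' Recording-level summaries for a whole cohort dataset
#'
#' Computes, per recording, the reference feature vector (from the
#' majority-vote annotation labels) and, when classifier predictions are
#' given, the prediction-based feature vector over the same carrying
#' filter.
#'
#' @param dataset From [frame_dataset()].
#' @param pred_posture,pred_movement Named lists of `frame_predictions`
#'   aligned with `dataset` (e.g. from [train_cross_validated()]).
#' @param sensibility Sensibility matrix.
#' @return List with `ref` (n x 34 matrix), `pred` (or `NULL`),
#'   `ages` and `recording_ids`.
#' @export
cohort_summaries <- function(dataset, pred_posture = NULL,
                             pred_movement = NULL,
                             sensibility = sensibility_matrix()) {
  ids <- names(dataset)
  ref <- t(vapply(dataset, function(el) {
    mask <- el$posture$valid & el$movement$valid
    summary_features(labels_onehot(el$posture),
                     labels_onehot(el$movement), mask, sensibility)
  }, numeric(7L + length(sensible_combinations(sensibility)))))
  pred <- NULL
  if (!is.null(pred_posture) && !is.null(pred_movement)) {
    pred <- t(vapply(ids, function(id) {
      pp <- pred_posture[[id]]; pm <- pred_movement[[id]]
      mask <- pp$valid_mask & pm$valid_mask
      summary_features(pp$onehot, pm$onehot, mask, sensibility)
    }, numeric(ncol(ref))))
    rownames(pred) <- ids
  }
  list(ref = ref, pred = pred,
       ages = vapply(dataset, `[[`, 0, "age_months"),
       recording_ids = ids)
}

#' Per-category correlations between predicted and reference distributions
#'
#' Concatenates each category's recording-level distribution values
#' across recordings and correlates the classifier-based variant with the
#' annotation-based reference (Pearson r with a recording-level bootstrap
#' CI).
#'
#' @param pred,ref Recordings x categories matrices of distribution
#'   values (same recordings, same category columns).
#' @param n_iter Bootstrap iterations.
#' @return Data frame with one row per category: `category`, `r`, `p`,
#'   `ci_lo`, `ci_hi` (`NA` where the category never occurs).
#' @export
distribution_correlations <- function(pred, ref, n_iter = 10000L) {
  stopifnot(all(dim(pred) == dim(ref)))
  cats <- colnames(ref) %||% paste0("cat", seq_len(ncol(ref)))
  rows <- lapply(seq_len(ncol(ref)), function(j) {
    a <- pred[, j]; b <- ref[, j]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(data.frame(category = cats[j], r = NA_real_, p = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    sr <- pearson_r(a[ok], b[ok], n_iter = n_iter)
    data.frame(category = cats[j], r = sr$statistic, p = sr$p,
               ci_lo = sr$lo, ci_hi = sr$hi)
  })
  do.call(rbind, rows)
}

#' Fit the holistic motor-score (BIMS) regressor
#'
#' BIMS is defined as the statistical expectation of the age most likely
#' to have generated a recording's distribution features, normalized to
#' `[0, 100]`. A Gaussian-process regressor (squared-exponential kernel
#' plus white noise, hyperparameters by marginal-likelihood optimization)
#' maps the 34-dimensional feature vector to age; the training age span
#' is then mapped linearly onto `[0, 100]` and predictions are clamped.
#'
#' @param features Recordings x features matrix (annotation-derived
#'   reference distributions).
#' @param ages_months Chronological ages, one per recording (spanning at
#'   least 6 months over at least 10 recordings).
#' @return An object of class `bims_model`.
#' @export
fit_bims <- function(features, ages_months) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(ages_months))
  if (nrow(features) < 10L) {
    stop("fit_bims: at least 10 training recordings are required")
  }
  if (diff(range(ages_months)) < 6) {
    stop("fit_bims: training ages must span at least 6 months")
  }
  sds <- apply(features, 2L, stats::sd)
  if (all(sds == 0)) stop("fit_bims: degenerate (zero-variance) features")
  center <- colMeans(features)
  scale <- ifelse(sds > 0, sds, 1)
  X <- sweep(sweep(features, 2L, center), 2L, scale, `/`)
  y <- ages_months
  ymean <- mean(y)
  yc <- y - ymean
  d2 <- as.matrix(stats::dist(X))^2
  med <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med) || med <= 0) med <- 1
  nlml <- function(par) {
    ell2 <- exp(2 * par[1L]); sf2 <- exp(2 * par[2L])
    sn2 <- exp(2 * par[3L])
    K <- sf2 * exp(-0.5 * d2 / ell2)
    diag(K) <- diag(K) + sn2 + 1e-8
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * alpha) + sum(log(diag(ch))) +
      0.5 * length(yc) * log(2 * pi)
  }
  start <- c(0.5 * log(med), log(stats::sd(y)), log(0.3 * stats::sd(y)))
  opt <- stats::optim(start, nlml, method = "Nelder-Mead",
                      control = list(maxit = 400))
  ell2 <- exp(2 * opt$par[1L]); sf2 <- exp(2 * opt$par[2L])
  sn2 <- exp(2 * opt$par[3L])
  K <- sf2 * exp(-0.5 * d2 / ell2)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(list(X = X, center = center, scale = scale,
                 alpha = alpha, ell2 = ell2, sf2 = sf2, sn2 = sn2,
                 ymean = ymean, age_span = range(ages_months),
                 nlml = opt$value),
            class = "bims_model")
}

#' Predict BIMS scores for feature vectors
#'
#' @param model A `bims_model`.
#' @param features Matrix (or single vector) of length-34 features.
#' @return Numeric BIMS scores in `[0, 100]`.
#' @export
predict_bims <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != length(model$center)) {
    stop("predict_bims: feature length does not match the model")
  }
  Xs <- sweep(sweep(features, 2L, model$center), 2L, model$scale, `/`)
  # squared distances to training points
  d2 <- outer(rowSums(Xs^2), rowSums(model$X^2), `+`) -
    2 * tcrossprod(Xs, model$X)
  d2[d2 < 0] <- 0
  Ks <- model$sf2 * exp(-0.5 * d2 / model$ell2)
  age_pred <- as.numeric(Ks %*% model$alpha) + model$ymean
  span <- model$age_span
  pmin(100, pmax(0, 100 * (age_pred - span[1L]) / diff(span)))
}

#' @param bims_ref,bims_pred Reference and predicted scores.
#' @return `delta_bims()` returns `bims_ref - bims_pred`.
#' @rdname predict_bims
#' @export
delta_bims <- function(bims_ref, bims_pred) bims_ref - bims_pred

#' Recording-level cross-validated BIMS scores
#'
#' Each recording's score comes from a model that never saw it: the
#' cohort is split into folds, the GP is fitted on the remaining
#' recordings' reference features, and both the reference score (from
#' reference features) and the predicted score (from classifier-derived
#' features) are computed for the held-out recordings.
#'
#' @param features_ref Reference (annotation-derived) feature matrix.
#' @param features_pred Classifier-derived feature matrix (optional).
#' @param ages_months Ages per recording.
#' @param folds,seed Cross-validation layout.
#' @return Data frame with `bims_ref`, and `bims_pred`/`delta` when
#'   predicted features are given.
#' @export
bims_cross_validated <- function(features_ref, features_pred = NULL,
                                 ages_months, folds = 5L, seed = 1L) {
  n <- nrow(features_ref)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  bims_ref <- numeric(n)
  bims_pred <- if (!is.null(features_pred)) numeric(n)
  for (f in seq_len(folds)) {
    hold <- fold == f
    model <- fit_bims(features_ref[!hold, , drop = FALSE],
                      ages_months[!hold])
    bims_ref[hold] <- predict_bims(model,
                                   features_ref[hold, , drop = FALSE])
    if (!is.null(features_pred)) {
      bims_pred[hold] <- predict_bims(model,
                                      features_pred[hold, ,
                                                    drop = FALSE])
    }
  }
  out <- data.frame(fold = fold, age_months = ages_months,
                    bims_ref = bims_ref)
  if (!is.null(features_pred)) {
    out$bims_pred <- bims_pred
    out$delta <- delta_bims(bims_ref, bims_pred)
  }
  out
}
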