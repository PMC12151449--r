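#' Compound confusion matrix over recordings and annotator comparisons
#'
#' Frame-level performance is computed from a single compound confusion
#' matrix: each individual human annotation is compared with the
#' classifier output, one comparison per (frame, annotator) pair, and the
#' per-recording matrices are summed elementwise. In inter-rater mode the
#' annotators are compared with each other in all pair combinations
#' instead. Masked frames are excluded.
#'
#' @param labels A `frame_labels` object (or a list of them, one per
#'   recording).
#' @param predictions A `frame_predictions` object aligned with `labels`
#'   (or a list of them); omit for inter-rater mode.
#' @return A K x K integer matrix with category dimnames; rows are the
#'   reference (annotator) labels, columns the compared labels.
#' @export
compound_confusion <- function(labels, predictions = NULL) {
  if (inherits(labels, "frame_labels")) {
    labels <- list(labels)
    if (!is.null(predictions)) predictions <- list(predictions)
  }
  categories <- labels[[1L]]$categories
  k <- length(categories)
  cm <- matrix(0L, k, k, dimnames = list(categories, categories))
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    if (is.null(predictions)) {
      n_ann <- ncol(lab$annotators)
      if (n_ann < 2L) stop("compound_confusion: inter-rater mode needs ",
                           ">= 2 annotators")
      for (a in seq_len(n_ann - 1L)) {
        for (b in seq.int(a + 1L, n_ann)) {
          cm <- cm + pair_confusion(lab$annotators[, a],
                                    lab$annotators[, b], lab$valid, k)
        }
      }
    } else {
      pred <- predictions[[i]]
      if (nrow(pred$onehot) != length(lab$target)) {
        stop("compound_confusion: frame grids are misaligned")
      }
      pred_idx <- max.col(pred$onehot, ties.method = "first")
      ok <- lab$valid & pred$valid_mask
      for (a in seq_len(ncol(lab$annotators))) {
        cm <- cm + pair_confusion(lab$annotators[, a], pred_idx, ok, k)
      }
    }
  }
  cm
}

pair_confusion <- function(ref, other, valid, k) {
  ok <- valid & !is.na(ref) & !is.na(other)
  m <- matrix(0L, k, k)
  if (any(ok)) {
    tab <- table(factor(ref[ok], levels = seq_len(k)),
                 factor(other[ok], levels = seq_len(k)))
    m <- m + unclass(tab)
  }
  m
}

#' Cohen kappa from a confusion matrix
#'
#' Multiclass chance-corrected agreement computed from the observed
#' agreement and the expected agreement under independent marginals. For
#' 2 x 2 matrices this reduces exactly to the binary closed form
#' `2 (tp*tn - fn*fp) / ((tp+fp)(fp+tn) + (tp+fn)(fn+tn))`. When all mass
#' lies in a single row and column the statistic is undefined and
#' `NA_real_` is returned.
#'
#' @param cm Square non-negative count matrix.
#' @return Kappa in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  if (n <= 0) stop("cohen_kappa: empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Recording-level percentile bootstrap confidence interval
#'
#' Resamples recordings with replacement and recomputes the statistic on
#' each resample; compound statistics are recompounded per resample. The
#' interval is the percentile interval of the bootstrap distribution.
#'
#' @param items List with one element per recording (per-recording values,
#'   confusion matrices, or anything the statistic consumes).
#' @param statistic Function mapping a list of items to a scalar.
#' @param n_iter Number of bootstrap iterations (default 10000).
#' @param conf Confidence level.
#' @return `list(lo, hi, estimate, n_iter)`.
#' @export
bootstrap_ci <- function(items, statistic, n_iter = 10000L,
                         conf = 0.95) {
  stopifnot(is.list(items), length(items) >= 2L)
  if (n_iter < 100L) {
    warning("bootstrap_ci: n_iter < 100 gives unstable intervals")
  }
  n <- length(items)
  est <- statistic(items)
  reps <- vapply(seq_len(n_iter), function(i) {
    statistic(items[sample.int(n, n, replace = TRUE)])
  }, numeric(1L))
  qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(lo = qs[1L], hi = qs[2L], estimate = est, n_iter = n_iter)
}

#' Statistical test results with significance tiers
#'
#' `stat_result` bundles a statistic, its p value, the 95% CI and a
#' significance tier string. Tier thresholds default to (.05, .005,
#' .001); the alternative printed convention (.05, .001, .0001) can be
#' selected via `thresholds`.
#'
#' @param statistic,p,lo,hi,n Components of the result.
#' @param flags Optional character vector of caveats.
#' @param thresholds Decreasing p-value thresholds for `*`, `**`, `***`.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(statistic, p, lo = NA_real_, hi = NA_real_,
                        n = NA_integer_, flags = character(0),
                        thresholds = c(0.05, 0.005, 0.001)) {
  structure(list(statistic = statistic, p = p, lo = lo, hi = hi, n = n,
                 tier = significance_tier(p, thresholds), flags = flags),
            class = "stat_result")
}

#' @param p A p value (or vector).
#' @rdname stat_result
#' @export
significance_tier <- function(p, thresholds = c(0.05, 0.005, 0.001)) {
  stopifnot(all(diff(thresholds) < 0))
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    paste(rep("*", sum(pp < thresholds)), collapse = "")
  }, "")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> stat=%.4g p=%.3g%s CI=[%.4g, %.4g] n=%s%s\n",
              x$statistic, x$p, x$tier, x$lo, x$hi, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = "; "),
                                          "]") else ""))
  invisible(x)
}

#' Two-tailed paired t test with a Gaussianity pre-check
#'
#' Tests the null hypothesis that paired differences are zero. The
#' Gaussianity of the differences is checked beforehand with a
#' one-sample Kolmogorov-Smirnov test of the standardized differences
#' against the standard normal (P > .05 expected); a failed pre-check is
#' flagged but the t test is still reported. All-zero differences make
#' the statistic undefined (`NA`).
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return A `stat_result` with the t statistic and two-tailed p.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  if (all(d == 0)) {
    return(stat_result(NA_real_, NA_real_, n = length(d),
                       flags = "degenerate: all differences zero"))
  }
  if (stats::sd(d) == 0) {
    # exactly constant nonzero shift: t statistic diverges
    return(stat_result(sign(mean(d)) * Inf, 0, n = length(d),
                       flags = "constant nonzero differences"))
  }
  flags <- character(0)
  if (stats::sd(d) > 0) {
    z <- (d - mean(d)) / stats::sd(d)
    ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
    if (ks$p.value <= 0.05) {
      flags <- sprintf("gaussianity pre-check failed (KS p=%.3g)",
                       ks$p.value)
    }
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_result(unname(tt$statistic), tt$p.value,
              lo = tt$conf.int[1L], hi = tt$conf.int[2L],
              n = length(d), flags = flags)
}

#' Pearson correlation with a recording-level bootstrap CI
#'
#' @param a,b Equal-length numeric vectors (n >= 3), one value per
#'   recording.
#' @param n_iter Bootstrap iterations for the CI.
#' @return A `stat_result` with r and the correlation-test p value;
#'   `NA` statistic when either input has zero variance.
#' @export
pearson_r <- function(a, b, n_iter = 10000L) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(stat_result(NA_real_, NA_real_, n = length(a),
                       flags = "degenerate: zero variance"))
  }
  ct <- stats::cor.test(a, b)
  items <- lapply(seq_along(a), function(i) c(a[i], b[i]))
  ci <- bootstrap_ci(items, function(it) {
    m <- do.call(rbind, it)
    if (stats::sd(m[, 1L]) == 0 || stats::sd(m[, 2L]) == 0) {
      return(NA_real_)
    }
    stats::cor(m[, 1L], m[, 2L])
  }, n_iter = n_iter)
  stat_result(unname(ct$estimate), ct$p.value, lo = ci$lo, hi = ci$hi,
              n = length(a))
}
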