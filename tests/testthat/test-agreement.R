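test_that("multiclass kappa equals the printed binary formula on 2x2 grids", {
  binary_kappa <- function(tp, fn, fp, tn) {
    denom <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
    ifelse(denom == 0, NA_real_, 2 * (tp * tn - fn * fp) / denom)
  }
  # dense grid here; the full exhaustive 0..50 sweep runs with the
  # acceptance suite
  g <- expand.grid(tp = seq(0, 50, 5), fn = seq(0, 50, 5),
                   fp = seq(0, 50, 5), tn = seq(0, 50, 5))
  set.seed(16)
  g <- rbind(g, data.frame(tp = sample(0:50, 200, TRUE),
                           fn = sample(0:50, 200, TRUE),
                           fp = sample(0:50, 200, TRUE),
                           tn = sample(0:50, 200, TRUE)))
  mk <- vapply(seq_len(nrow(g)), function(i) {
    m <- matrix(c(g$tp[i], g$fn[i], g$fp[i], g$tn[i]), 2L)
    if (sum(m) == 0) return(NA_real_)
    cohen_kappa(m)
  }, numeric(1))
  bk <- binary_kappa(g$tp, g$fn, g$fp, g$tn)
  nonempty <- rowSums(g) > 0
  ok <- nonempty & !is.na(bk)
  expect_lt(max(abs(mk[ok] - bk[ok])), 1e-12)
  expect_identical(is.na(mk[nonempty]), is.na(bk[nonempty]))
})

test_that("kappa has the expected fixed points and invariances", {
  expect_equal(cohen_kappa(diag(c(10, 20, 5))), 1)
  expect_equal(cohen_kappa(matrix(25, 2, 2)), 0)
  expect_equal(cohen_kappa(matrix(c(40, 5, 10, 45), 2)), 0.70)
  expect_true(is.na(cohen_kappa(matrix(c(7, 0, 0, 0), 2))))
  expect_error(cohen_kappa(matrix(0, 3, 3)), "empty")
  # invariant to simultaneous row+column permutation
  set.seed(11)
  cm <- matrix(rpois(25, 8), 5)
  perm <- sample(5)
  expect_equal(cohen_kappa(cm), cohen_kappa(cm[perm, perm]))
})

test_that("compounding is order-invariant and counts annotator pairs", {
  mk_lab <- function(values, n_ann, seed) {
    set.seed(seed)
    ann <- matrix(values, length(values), n_ann)
    ann[sample(length(ann), 5)] <- sample(1:3, 5, replace = TRUE)
    structure(list(target = values, annotators = ann,
                   valid = rep(TRUE, length(values)),
                   categories = c("a", "b", "c"), track = "posture"),
              class = "frame_labels")
  }
  labs <- list(mk_lab(rep(1:3, 10), 3, 1), mk_lab(rep(c(2L, 3L), 15), 3, 2))
  cm12 <- compound_confusion(labs)
  cm21 <- compound_confusion(rev(labs))
  expect_equal(cohen_kappa(cm12), cohen_kappa(cm21))
  # 3 annotators -> 3 pair comparisons per frame
  expect_equal(sum(cm12), 3 * 60)
  # prediction mode: 2 annotators -> total = 2 x valid frames
  lab2 <- mk_lab(rep(1:3, 8), 2, 3)
  onehot <- matrix(0L, 24, 3)
  onehot[cbind(1:24, lab2$target)] <- 1L
  pred <- frame_predictions(seq_len(24), onehot, rep(TRUE, 24))
  cmp <- compound_confusion(lab2, pred)
  expect_equal(sum(cmp), 2 * 24)
  # identical prediction and single annotator -> diagonal matrix
  lab1 <- structure(list(target = rep(1:3, 8),
                         annotators = matrix(rep(1:3, 8), ncol = 1),
                         valid = rep(TRUE, 24),
                         categories = c("a", "b", "c"),
                         track = "posture"), class = "frame_labels")
  cmd <- compound_confusion(lab1, pred)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
})

test_that("bootstrap CI behaves on degenerate and nested inputs", {
  items <- as.list(rep(0.5, 10))
  ci <- bootstrap_ci(items, function(x) mean(unlist(x)), n_iter = 200)
  expect_equal(ci$lo, 0.5)
  expect_equal(ci$hi, 0.5)
  set.seed(12)
  vals <- as.list(rnorm(15))
  ci2 <- bootstrap_ci(vals, function(x) mean(unlist(x)), n_iter = 500)
  expect_lte(ci2$lo, ci2$estimate)
  expect_gte(ci2$hi, ci2$estimate)
  expect_warning(bootstrap_ci(vals, function(x) mean(unlist(x)),
                              n_iter = 50), "unstable")
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  set.seed(13)
  width <- function(n) {
    vals <- as.list(rnorm(n))
    ci <- bootstrap_ci(vals, function(x) mean(unlist(x)), n_iter = 800)
    ci$hi - ci$lo
  }
  w10 <- mean(replicate(8, width(10)))
  w90 <- mean(replicate(8, width(90)))
  expect_lt(w90, w10 / 1.8)
  expect_gt(w90, w10 / 6)
})

test_that("paired t handles shifts, ties and the Gaussianity pre-check", {
  x <- rnorm(9, sd = 1e-9) + 5
  res <- paired_t(x + 1, x)
  expect_lt(res$p, 1e-6)
  res0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(res0$statistic))
  expect_match(res0$flags, "zero")
  # strongly non-Gaussian differences are flagged but still tested
  set.seed(14)
  y <- rnorm(60)
  res2 <- paired_t(y + rexp(60)^3, y)
  expect_true(length(res2$flags) == 1)
  expect_false(is.na(res2$p))
})

test_that("pearson_r recovers exact and sampled correlations", {
  a <- c(1, 2, 3, 4.5, 7)
  expect_equal(pearson_r(a, 2 * a + 1, n_iter = 200)$statistic, 1)
  expect_equal(pearson_r(a, -a, n_iter = 200)$statistic, -1)
  expect_true(is.na(pearson_r(a, rep(2, 5), n_iter = 200)$statistic))
  set.seed(15)
  n <- 200
  z <- rnorm(n)
  x <- z + rnorm(n, sd = sqrt(1 / 0.8^2 - 1))
  r <- pearson_r(x, z, n_iter = 500)$statistic
  expect_lt(abs(r - 0.8), 0.08)
})

test_that("significance tiers follow the configured legend", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.004, 5e-4)),
               c("", "*", "**", "***"))
  expect_equal(significance_tier(0.004, c(0.05, 0.001, 1e-4)), "*")
})
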