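onehot_of <- function(idx, k) {
  oh <- matrix(0L, length(idx), k)
  oh[cbind(seq_along(idx), idx)] <- 1L
  oh
}

test_that("category distributions are carrying-filtered frame means", {
  oh <- onehot_of(c(1, 1, 1, 2, 2, 3, 3, 3, 3, 3), 3)
  expect_equal(category_distribution(oh), c(0.3, 0.2, 0.5))
  expect_equal(sum(category_distribution(oh)), 1)
  # delta distribution
  expect_equal(category_distribution(onehot_of(rep(2, 6), 3)),
               c(0, 1, 0))
  # mask removing all frames of one category renormalizes the rest
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, rep(TRUE, 5))
  expect_equal(category_distribution(oh, mask), c(3 / 8, 0, 5 / 8))
  expect_true(all(is.na(category_distribution(oh, rep(FALSE, 10)))))
})

test_that("the default sensibility matrix has the required structure", {
  s <- sensibility_matrix()
  expect_equal(sum(s), 27)
  expect_true(s["standing", "fluent"])
  expect_false(s["supine", "fluent"])
  expect_true(all(s[, "still"]))
  expect_equal(length(sensible_combinations()), 27)
  expect_true("prone-pivot_left" %in% sensible_combinations())
})

test_that("conditioned distributions drop non-sensible frames and renormalize", {
  k_p <- 7; k_m <- 9
  p_standing <- match("standing", posture_categories())
  m_fluent <- match("fluent", movement_categories())
  po <- onehot_of(rep(p_standing, 5), k_p)
  mo <- onehot_of(rep(m_fluent, 5), k_m)
  cd <- conditioned_distribution(po, mo)
  expect_equal(unname(cd["standing-fluent"]), 1)
  expect_equal(sum(cd), 1)
  # a supine-fluent frame is excluded
  p_supine <- match("supine", posture_categories())
  po2 <- onehot_of(c(rep(p_standing, 18), rep(p_supine, 2)), k_p)
  mo2 <- onehot_of(rep(m_fluent, 20), k_m)
  cd2 <- conditioned_distribution(po2, mo2)
  expect_equal(unname(cd2["standing-fluent"]), 1)  # 18/18 after dropping
  # mixed fixture: 20 frames, 2 non-sensible -> weights = counts/18
  p_prone <- match("prone", posture_categories())
  m_still <- match("still", movement_categories())
  po3 <- onehot_of(c(rep(p_standing, 12), rep(p_prone, 6),
                     rep(p_supine, 2)), k_p)
  mo3 <- onehot_of(c(rep(m_fluent, 12), rep(m_still, 6),
                     rep(m_fluent, 2)), k_m)
  cd3 <- conditioned_distribution(po3, mo3)
  expect_equal(unname(cd3["standing-fluent"]), 12 / 18)
  expect_equal(unname(cd3["prone-still"]), 6 / 18)
  expect_true(all(is.na(conditioned_distribution(
    onehot_of(rep(p_supine, 3), k_p), onehot_of(rep(m_fluent, 3), k_m)))))
})

test_that("conditioned mass never exceeds the posture marginal", {
  set.seed(41)
  k_p <- 7; k_m <- 9
  sens <- sensibility_matrix()
  for (rep_i in 1:5) {
    p_idx <- sample(k_p, 60, TRUE)
    m_idx <- sample(k_m, 60, TRUE)
    po <- onehot_of(p_idx, k_p); mo <- onehot_of(m_idx, k_m)
    cd <- conditioned_distribution(po, mo)
    if (all(is.na(cd))) next
    sensible <- sens[cbind(p_idx, m_idx)]
    n_sens <- sum(sensible)
    # undo renormalization: counts over sensible frames
    counts <- cd * n_sens
    marg <- vapply(posture_categories(), function(pc)
      sum(counts[startsWith(names(cd), paste0(pc, "-"))]), 0)
    raw_post <- tabulate(p_idx, k_p)
    expect_true(all(marg <= raw_post + 1e-9))
  }
})

test_that("distribution correlations are exact for identical inputs and near zero under independence", {
  set.seed(42)
  ref <- matrix(runif(40 * 5), 40)
  ref <- ref / rowSums(ref)
  colnames(ref) <- letters[1:5]
  dc <- distribution_correlations(ref, ref, n_iter = 200)
  expect_equal(dc$r, rep(1, 5), tolerance = 1e-12)
  indep <- matrix(runif(40 * 5), 40)
  indep <- indep / rowSums(indep)
  colnames(indep) <- letters[1:5]
  dc2 <- distribution_correlations(indep, ref, n_iter = 200)
  expect_true(all(abs(dc2$r) < 0.35))
})

test_that("the BIMS regressor recovers a monotone age signal", {
  set.seed(43)
  n <- 30
  ages <- runif(n, 4.5, 16.6)
  a <- (ages - 4.5) / 12.1
  feats <- cbind(supine = 0.5 - 0.4 * a, crawl = 0.2 + 0.1 * a,
                 standing = 0.05 + 0.3 * a,
                 noise = runif(n, 0, 0.05))
  feats <- feats + matrix(rnorm(n * 4, 0, 0.02), n)
  model <- fit_bims(feats, ages)
  pred <- predict_bims(model, feats)
  expect_true(all(pred >= 0 & pred <= 100))
  expect_gt(cor(pred, ages), 0.9)
  # duplicated features with different ages predict between the two
  feats2 <- rbind(feats, feats[1, ], feats[1, ])
  ages2 <- c(ages, ages[1] - 1.5, ages[1] + 1.5)
  m2 <- fit_bims(feats2, ages2)
  p2 <- predict_bims(m2, feats[1, , drop = FALSE])
  span <- range(ages2)
  age_back <- span[1] + p2 / 100 * diff(span)
  expect_gt(age_back, ages[1] - 1.5)
  expect_lt(age_back, ages[1] + 1.5)
  # degenerate features refuse to fit
  expect_error(fit_bims(matrix(1, 12, 3), seq(5, 16, length.out = 12)),
               "degenerate")
  expect_error(predict_bims(model, feats[, 1:2]), "length")
})

test_that("BIMS depends only on the summary vector, not recording length", {
  # identical distributions from different length recordings
  k_p <- 7; k_m <- 9
  p_idx_short <- rep(c(1, 5), times = c(4, 4))
  p_idx_long <- rep(c(1, 5), times = c(40, 40))
  m_idx_short <- rep(1, 8); m_idx_long <- rep(1, 80)
  f_short <- summary_features(onehot_of(p_idx_short, k_p),
                              onehot_of(m_idx_short, k_m))
  f_long <- summary_features(onehot_of(p_idx_long, k_p),
                             onehot_of(m_idx_long, k_m))
  expect_equal(f_short, f_long)
  expect_length(f_short, 34L)
  expect_equal(sum(f_short[1:7]), 1)
  expect_equal(sum(f_short[8:34]), 1)
})

test_that("cross-validated BIMS assigns out-of-fold scores", {
  set.seed(44)
  n <- 20
  ages <- runif(n, 4.5, 16.6)
  a <- (ages - 4.5) / 12.1
  ref <- cbind(0.6 - 0.5 * a, 0.1 + 0.2 * a, 0.3 + 0.3 * a) +
    matrix(rnorm(n * 3, 0, 0.03), n)
  pred_f <- ref + matrix(rnorm(n * 3, 0, 0.05), n)
  out <- bims_cross_validated(ref, pred_f, ages, folds = 4, seed = 2)
  expect_equal(nrow(out), n)
  expect_true(all(out$bims_ref >= 0 & out$bims_ref <= 100))
  expect_equal(out$delta, out$bims_ref - out$bims_pred)
  expect_gt(cor(out$bims_ref, ages), 0.85)
})
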