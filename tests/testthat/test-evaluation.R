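test_that("Tanimoto coefficient matches set counting", {
  ref <- array(c(1, 1, 2, 2, 3, 3), c(2, 3))
  expect_equal(tanimoto(ref, ref, 1), 1)
  auto <- array(c(2, 2, 1, 1, 3, 3), c(2, 3))
  expect_equal(tanimoto(auto, ref, 1), 0)        # disjoint CSF assignments
  # constructed counts: v_ART = 30, v_AT = 40, v_RT = 50 -> 30/60
  auto2 <- c(rep(1, 40), rep(2, 60))
  ref2 <- c(rep(1, 30), rep(2, 10), rep(1, 20), rep(2, 40))
  expect_equal(tanimoto(auto2, ref2, 1), 0.5)
  expect_warning(tc0 <- tanimoto(c(1, 1), c(1, 1), 3), "absent")
  expect_equal(tc0, 0)
})

test_that("Jaccard similarity equals intersection over union", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  b <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(jaccard(a, b), sum(a & b) / sum(a | b))
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
})

test_that("TC and JS agree with brute-force counting on random label maps", {
  set.seed(31)
  for (trial in 1:100) {
    auto <- sample(0:3, 60, replace = TRUE)
    ref <- sample(0:3, 60, replace = TRUE)
    ti <- sample(1:3, 1)
    v_art <- sum(auto == ti & ref == ti)
    v_at <- sum(auto == ti); v_rt <- sum(ref == ti)
    if (v_at + v_rt - v_art == 0) next
    expect_equal(tanimoto(auto, ref, ti), v_art / (v_at + v_rt - v_art))
    expect_equal(jaccard(auto == ti, ref == ti),
                 tanimoto(auto, ref, ti))   # same formula on the same masks
  }
})

test_that("confusion-derived rates reproduce hand-computed values", {
  pred <- c(rep("ad", 11), rep("nor", 9))
  truth <- c(rep("ad", 9), rep("nor", 2), rep("ad", 1), rep("nor", 8))
  cc <- confusion(pred, truth, positive = "ad")
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 9L, FP = 2L, TN = 8L, FN = 1L))
  expect_equal(sensitivity(cc), 0.9)
  expect_equal(specificity(cc), 0.8)
  expect_equal(accuracy(cc), 0.85)
  # perfect predictions
  cp <- confusion(truth, truth, positive = "ad")
  expect_equal(c(sensitivity(cp), specificity(cp), accuracy(cp)), c(1, 1, 1))
  # all-negative predictions with positives present
  cn <- confusion(rep("nor", 20), truth, positive = "ad")
  expect_equal(sensitivity(cn), 0)
  # zero-denominator conventions: missing, not zero
  expect_true(is.na(sensitivity(confusion("nor", "nor", "ad"))))
  expect_true(is.na(specificity(confusion("ad", "ad", "ad"))))
})

test_that("rates are invariant under sample reordering", {
  set.seed(32)
  pred <- sample(c("ad", "nor"), 30, replace = TRUE)
  truth <- sample(c("ad", "nor"), 30, replace = TRUE)
  perm <- sample(30)
  c1 <- confusion(pred, truth, "ad")
  c2 <- confusion(pred[perm], truth[perm], "ad")
  expect_identical(unclass(c1), unclass(c2))
})

test_that("ROC/AUC equals the pairwise-concordance statistic", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), 1)$auc, 1)
  # reversed scores
  expect_equal(roc_auc(c(10, 11, 12, 1, 2), c(0, 0, 0, 1, 1), 1)$auc, 0)
  # 6-sample toy list with a tie
  sc <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  lb <- c(1, 0, 1, 1, 0, 0)
  expect_equal(roc_auc(sc, lb, 1)$auc, bf_auc(sc, lb, 1))
  # random instances, incl. heavy ties
  set.seed(33)
  for (trial in 1:25) {
    sc <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
    lb <- sample(0:1, 40, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb, 1)$auc, bf_auc(sc, lb, 1), tolerance = 1e-9)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1), 1), "both classes")
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(36)
  sc <- rnorm(50)
  lb <- sample(0:1, 50, replace = TRUE)
  expect_equal(roc_auc(sc, lb, 1)$auc,
               as.numeric(suppressMessages(pROC::auc(lb, sc,
                                                     direction = "<"))),
               tolerance = 1e-9)
})

test_that("ROC curve endpoints and EER behave sensibly", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), 1)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  eer <- equal_error_rate(r)
  expect_gte(eer, 0); expect_lte(eer, 1)
  # perfectly separated scores give EER 0
  expect_equal(equal_error_rate(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1), 1)), 0)
})

test_that("cross-validation produces stratified non-overlapping 70/30 splits", {
  set.seed(34)
  x <- matrix(rnorm(200), 100, 2)
  y <- rep(c("ad", "nor"), each = 50)
  fit_fun <- function(xt, yt) list(mu = colMeans(xt[yt == "ad", , drop = FALSE]))
  score_fun <- function(model, xt) -rowSums((xt - matrix(model$mu, nrow(xt), 2,
                                                         byrow = TRUE))^2) + 2
  cv <- cross_validate(x, y, fit_fun, score_fun, positive = "ad",
                       n_splits = 10, seed = 7)
  expect_equal(nrow(cv$folds), 10)
  expect_true(all(cv$folds$n_train == 70))
  expect_true(all(cv$folds$n_test == 30))
  # deterministic under the seed
  cv2 <- cross_validate(x, y, fit_fun, score_fun, positive = "ad",
                        n_splits = 10, seed = 7)
  expect_identical(cv$folds, cv2$folds)
  expect_named(cv$summary, c("se", "sp", "ca", "auc"))
  expect_true(all(vapply(cv$summary, function(s) s$q1 <= s$median &&
                           s$median <= s$q3, TRUE)))
})

test_that("constant-prediction model scores the class prevalence", {
  set.seed(35)
  x <- matrix(rnorm(120), 60, 2)
  y <- rep(c("ad", "nor"), c(24, 36))
  fit_fun <- function(xt, yt) NULL
  score_fun <- function(model, xt) rep(1, nrow(xt))   # always accept
  cv <- cross_validate(x, y, fit_fun, score_fun, positive = "ad",
                       n_splits = 5, seed = 2)
  # every test split is stratified: 8 ad / 11 nor (24*0.3 / 36*0.3 rounded)
  prev <- vapply(seq_len(5), function(i) {
    cv$folds$ca[i]
  }, 0)
  expect_true(all(abs(prev - 8 / 19) < 0.06))
  expect_true(all(cv$folds$se == 1))
  expect_true(all(cv$folds$sp == 0))
})

test_that("disjoint k-fold option covers every sample exactly once", {
  x <- matrix(rnorm(80), 40, 2)
  y <- rep(c("a", "b"), each = 20)
  fit_fun <- function(xt, yt) NULL
  score_fun <- function(model, xt) rnorm(nrow(xt))
  cv <- cross_validate(x, y, fit_fun, score_fun, positive = "a",
                       n_splits = 4, method = "kfold", seed = 3)
  expect_equal(sum(cv$folds$n_test), 40)
})

test_that("boxplot summary flags outliers by the IQR rule", {
  s <- fuzzyfuse:::boxplot_summary(c(0.40, 0.45, 0.50, 0.50, 0.55, 0.60, 5))
  expect_equal(s$n_extreme_outliers, 1)   # 5 is beyond Q3 + 3 IQR
  expect_equal(s$n_mild_outliers, 0)
  expect_equal(s$median, 0.5)
})
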