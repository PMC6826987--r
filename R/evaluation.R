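#' Tanimoto coefficient for one tissue
#'
#' Overlap between an automated and a reference labeling for tissue `T`:
#' \eqn{TC(T) = v_{ART} / (v_{AT} + v_{RT} - v_{ART})}, where \eqn{v_{ART}}
#' counts voxels assigned to `T` by both labelings and \eqn{v_{AT}},
#' \eqn{v_{RT}} the per-labeling counts. 1 means identical assignments,
#' 0 no shared voxels. When neither labeling contains the tissue the value
#' is 0 by convention with a warning.
#'
#' @param auto automated integer label array.
#' @param ref reference (ground-truth) label array.
#' @param tissue tissue id (integer label value).
#' @return Scalar TC in `[0,1]`.
#' @export
tanimoto <- function(auto, ref, tissue) {
  if (length(auto) != length(ref)) stop("label maps must share the grid")
  a <- auto == tissue
  r <- ref == tissue
  v_art <- sum(a & r)
  v_at <- sum(a)
  v_rt <- sum(r)
  denom <- v_at + v_rt - v_art
  if (denom == 0) {
    warning("tissue absent from both labelings; TC = 0 by convention",
            call. = FALSE)
    return(0)
  }
  v_art / denom
}

#' Jaccard similarity of two masks
#'
#' \eqn{JS = |S \cap G| / |S \cup G|} between a segmented mask and the
#' ground-truth mask; equals the Tanimoto coefficient computed on the same
#' single-tissue masks.
#'
#' @param seg,truth logical arrays (or anything coercible).
#' @return Scalar JS in `[0,1]` (0 when both masks are empty, with warning).
#' @export
jaccard <- function(seg, truth) {
  s <- as.logical(seg); g <- as.logical(truth)
  if (length(s) != length(g)) stop("masks must share the grid")
  uni <- sum(s | g)
  if (uni == 0) {
    warning("both masks empty; JS = 0 by convention", call. = FALSE)
    return(0)
  }
  sum(s & g) / uni
}

#' Confusion counts
#'
#' @param pred predicted labels (factor/vector).
#' @param truth true labels.
#' @param positive the positive class value.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(pred, truth, positive) {
  if (length(pred) != length(truth)) stop("length mismatch")
  p <- pred == positive
  t <- truth == positive
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' @rdname confusion
#' @param cc a `confusion_counts` object.
#' @return `sensitivity`/`specificity`/`accuracy` return scalars in `[0,1]`;
#'   `NA` when the corresponding denominator is zero (no positives /
#'   negatives present).
#' @export
sensitivity <- function(cc) {
  if (cc$TP + cc$FN == 0) return(NA_real_)
  cc$TP / (cc$TP + cc$FN)
}

#' @rdname confusion
#' @export
specificity <- function(cc) {
  if (cc$TN + cc$FP == 0) return(NA_real_)
  cc$TN / (cc$TN + cc$FP)
}

#' @rdname confusion
#' @export
accuracy <- function(cc) {
  n <- cc$TP + cc$FP + cc$TN + cc$FN
  if (n == 0) return(NA_real_)
  (cc$TP + cc$TN) / n
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (classifying a sample
#' positive when `score >= threshold`), collects (FPR, TPR) pairs and
#' integrates the area under the curve with the trapezoid rule. With tied
#' scores this equals the Mann–Whitney concordance statistic (ties counted
#' 1/2).
#'
#' @param scores per-sample continuous scores; larger = more positive.
#' @param labels true labels.
#' @param positive positive class value.
#' @return List of class `roc_result`: `curve` (data.frame with `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive) {
  y <- labels == positive
  if (!any(y) || all(y)) stop("need both classes for a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(y); Ng <- sum(!y)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / P, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / Ng, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

#' Equal error rate
#'
#' Operating point where the false positive rate equals the false negative
#' rate (1 - TPR), located by linear interpolation along the ROC curve.
#'
#' @param roc a [roc_auc()] result.
#' @return Scalar EER in `[0,1]`.
#' @export
equal_error_rate <- function(roc) {
  cv <- roc$curve
  fnr <- 1 - cv$tpr
  d <- cv$fpr - fnr
  k <- which(diff(sign(d)) != 0)
  if (length(k) == 0L) return(cv$fpr[which.min(abs(d))])
  k <- k[1L]
  # linear interpolation between bracketing points
  w <- d[k] / (d[k] - d[k + 1L])
  (1 - w) * cv$fpr[k] + w * cv$fpr[k + 1L]
}

boxplot_summary <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, na.rm = TRUE)
  iqr <- q[4] - q[2]
  mild <- x > q[4] + 1.5 * iqr | x < q[2] - 1.5 * iqr
  extreme <- x > q[4] + 3 * iqr | x < q[2] - 3 * iqr
  list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x),
       min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       n_mild_outliers = sum(mild & !extreme, na.rm = TRUE),
       n_extreme_outliers = sum(extreme, na.rm = TRUE))
}

#' Cross-validation harness
#'
#' Repeated stratified random resampling: `n_splits` independent 70/30
#' train/test partitions (each class split separately, so splits are
#' stratified and train/test never overlap), or optionally standard disjoint
#' k-fold. Each split fits a model on the training part, scores the test
#' part, and records SE, SP, CA and AUC; the summary reports mean, standard
#' deviation and the five-number boxplot statistics with mild/extreme
#' outlier counts.
#'
#' @param x feature matrix.
#' @param y class labels (two classes).
#' @param fit_fun `function(x_train, y_train)` returning a model.
#' @param score_fun `function(model, x_test)` returning a numeric score per
#'   row; larger = more `positive`. Classification uses `score >= 0`.
#' @param positive the positive class value.
#' @param n_splits number of resamples (or folds).
#' @param train_fraction training fraction per resample.
#' @param method `"resample"` (random 70/30 partitions) or `"kfold"`.
#' @param seed RNG seed; fixes every split.
#' @return List of class `cv_result`: `folds` (data.frame of per-split
#'   metrics) and `summary` (per-metric boxplot statistics).
#' @export
cross_validate <- function(x, y, fit_fun, score_fun, positive,
                           n_splits = 10L, train_fraction = 0.7,
                           method = c("resample", "kfold"), seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.vector(y)
  n <- nrow(x)
  cls <- split(seq_len(n), y)
  splits <- with_seed(seed, {
    if (method == "resample") {
      lapply(seq_len(n_splits), function(s) {
        tr <- unlist(lapply(cls, function(idx) {
          sample(idx, round(train_fraction * length(idx)))
        }), use.names = FALSE)
        list(train = sort(tr), test = setdiff(seq_len(n), tr))
      })
    } else {
      fold_of <- integer(n)
      for (idx in cls) fold_of[idx] <- sample(rep_len(seq_len(n_splits), length(idx)))
      lapply(seq_len(n_splits), function(s) {
        list(train = which(fold_of != s), test = which(fold_of == s))
      })
    }
  })
  rows <- lapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    model <- fit_fun(x[sp$train, , drop = FALSE], y[sp$train])
    sc <- score_fun(model, x[sp$test, , drop = FALSE])
    yt <- y[sp$test]
    pred <- ifelse(sc >= 0, "pos", "neg")
    cc <- confusion(pred, ifelse(yt == positive, "pos", "neg"), "pos")
    auc <- if (length(unique(yt)) == 2L) roc_auc(sc, yt, positive)$auc else NA_real_
    data.frame(split = s, n_train = length(sp$train), n_test = length(sp$test),
               se = sensitivity(cc), sp = specificity(cc), ca = accuracy(cc),
               auc = auc)
  })
  folds <- do.call(rbind, rows)
  summ <- lapply(c(se = "se", sp = "sp", ca = "ca", auc = "auc"),
                 function(mm) boxplot_summary(folds[[mm]]))
  structure(list(folds = folds, summary = summ, method = method),
            class = "cv_result")
}
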