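## Discrimination metrics: AUROC, ROC curves, stratified bootstrap CIs,
## threshold metrics. Positive class = paclitaxel-sensitive throughout.

.asBinaryLabels <- function(labels) {
  if (is.factor(labels)) {
    if ("excluded" %in% levels(labels) && any(labels == "excluded"))
      stop("labels contain 'excluded' patients", call. = FALSE)
    y <- as.integer(labels == "sensitive")
  } else if (is.logical(labels)) {
    y <- as.integer(labels)
  } else if (is.character(labels)) {
    y <- as.integer(labels == "sensitive")
  } else {
    stopifnot(all(labels %in% c(0, 1)))
    y <- as.integer(labels)
  }
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  y
}

#' Area under the ROC curve
#'
#' Mann-Whitney pair-counting statistic: the probability that a random
#' positive outscores a random negative, with tied pairs receiving half
#' credit (mid-rank convention). Computed via ranks in O(n log n).
#'
#' @param scores Numeric scores (higher = more likely sensitive).
#' @param labels Binary labels; factors use `sensitive` as the positive
#'   class, `excluded` entries are refused.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))  # 2/3
#' @export
auroc <- function(scores, labels) {
  y <- .asBinaryLabels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  r <- rank(scores)  # average ranks handle ties
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve points
#'
#' One `(fpr, tpr, threshold)` point per distinct score (predicting positive
#' at `score >= threshold`), preceded by the (0, 0) endpoint. The trapezoidal
#' area under the returned polyline equals [auroc()] exactly.
#'
#' @inheritParams auroc
#' @return `data.frame` with columns `fpr`, `tpr`, `threshold`; starts at
#'   (0, 0) with threshold `Inf` and ends at (1, 1).
#' @export
rocCurve <- function(scores, labels) {
  y <- .asBinaryLabels(labels)
  stopifnot(length(scores) == length(y))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last row of each tie block
  tp <- cumsum(yy)[last]; fp <- cumsum(1 - yy)[last]
  data.frame(fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos),
             threshold = c(Inf, s[last]))
}

#' Stratified percentile bootstrap CI for the AUROC
#'
#' Resamples positives and negatives separately (so every resample keeps both
#' classes), recomputes the AUROC `nBoot` times and reports the percentile
#' interval. Deterministic given `seed`.
#'
#' @inheritParams auroc
#' @param nBoot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrapAurocCI <- function(scores, labels, nBoot = 2000, level = 0.95,
                             seed = 1L) {
  y <- .asBinaryLabels(labels)
  stopifnot(length(scores) == length(y), nBoot >= 1, level > 0, level < 1)
  sPos <- scores[y == 1L]; sNeg <- scores[y == 0L]
  nPos <- length(sPos); nNeg <- length(sNeg)
  set.seed(seed)
  aucs <- vapply(seq_len(nBoot), function(b) {
    bp <- sPos[sample.int(nPos, nPos, replace = TRUE)]
    bn <- sNeg[sample.int(nNeg, nNeg, replace = TRUE)]
    r <- rank(c(bp, bn))
    (sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }, numeric(1))
  alpha <- 1 - level
  ci <- unname(quantile(aucs, c(alpha / 2, 1 - alpha / 2)))
  c(lower = ci[1], upper = ci[2])
}

#' Threshold classification metrics
#'
#' Predicts positive at `score >= threshold` and reports sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), accuracy and F1 = 2TP/(2TP+FP+FN),
#' with paclitaxel-sensitive as the positive class.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: `sensitivity`, `specificity`, `accuracy`, `f1`,
#'   `threshold`, `n_pos`, `n_neg`, and the confusion counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
thresholdMetrics <- function(scores, labels, threshold = 0.5) {
  y <- .asBinaryLabels(labels)
  stopifnot(length(scores) == length(y))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y),
       f1 = 2 * tp / (2 * tp + fp + fn),
       threshold = threshold, n_pos = tp + fn, n_neg = tn + fp,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# full metrics block used by the pipeline report
.metricsReport <- function(scores, labels, threshold = 0.5, nBoot = 2000,
                           level = 0.95, seed = 1L) {
  tm <- thresholdMetrics(scores, labels, threshold)
  ci <- bootstrapAurocCI(scores, labels, nBoot = nBoot, level = level,
                         seed = seed)
  c(list(auroc = auroc(scores, labels),
         auroc_ci_lower = unname(ci["lower"]),
         auroc_ci_upper = unname(ci["upper"])), tm)
}
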