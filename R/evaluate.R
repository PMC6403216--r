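# ROC curve, AUC, Youden-index cutoff, and sensitivity/specificity at a
# cutoff. The positive class is class 1 (codel) and its probability score
# p1 is the ROC score; prediction at a cutoff is "positive iff score >=
# cutoff" (inclusive).

#' ROC curve and AUC
#'
#' The curve is built over all distinct score thresholds (plus `Inf`);
#' at threshold t a sample is predicted positive iff its score is `>= t`.
#' The trapezoidal AUC equals the Mann-Whitney pair statistic (fraction
#' of positive/negative pairs ranked correctly, ties counted 1/2). The
#' Youden-optimal cutoff (maximizing sensitivity + specificity - 1) is
#' attached, with ties broken toward the highest (most specific)
#' threshold.
#'
#' @param labels class labels (values in `{codel, no_codel}` or a factor);
#'   both classes must be present.
#' @param scores numeric scores (higher = more positive), e.g. the
#'   `p_codel` column of [forward_proba()].
#' @param positive label of the positive class (default `"codel"`).
#' @return an object of class `roc_curve`: `thresholds` (descending),
#'   `tpr`, `fpr`, `auc`, `youden_cutoff`, `youden_j`.
#' @export
roc_auc <- function(labels, scores, positive = "codel") {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  curve <- structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
                     class = "roc_curve")
  yj <- youden_cutoff(curve)
  curve$youden_cutoff <- yj$cutoff
  curve$youden_j <- yj$j
  curve
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 = tpr - fpr over the
#' curve's thresholds; ties are broken toward the highest threshold.
#'
#' @param curve a `roc_curve` from [roc_auc()].
#' @return list with `cutoff` and `j`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tpr - curve$fpr
  best <- which.max(j)  # thresholds are descending: first max = highest
  list(cutoff = curve$thresholds[best], j = j[best])
}

#' Sensitivity and specificity at a cutoff
#'
#' Predicts positive iff `score >= cutoff`; sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). If a class is absent its metric is `NA`
#' with a warning rather than silently 0.
#'
#' @inheritParams roc_auc
#' @param cutoff decision threshold.
#' @return named numeric vector `c(sensitivity=, specificity=)`.
#' @export
sens_spec_at <- function(labels, scores, cutoff, positive = "codel") {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores), is.finite(cutoff) ||
              is.infinite(cutoff))
  pos <- labels == positive
  pred <- scores >= cutoff
  sens <- if (any(pos)) sum(pred & pos) / sum(pos) else {
    warning("no positive samples: sensitivity undefined")
    NA_real_
  }
  spec <- if (any(!pos)) sum(!pred & !pos) / sum(!pos) else {
    warning("no negative samples: specificity undefined")
    NA_real_
  }
  c(sensitivity = sens, specificity = spec)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> %d thresholds; AUC = %.4f; Youden cutoff = %s (J = %.4f)\n",
    length(x$thresholds), x$auc, format(x$youden_cutoff, digits = 4),
    x$youden_j))
  invisible(x)
}

#' Evaluation report for a fitted model
#'
#' Scores a labeled feature set, computes the ROC/AUC, the Youden cutoff
#' (or uses a supplied cutoff, e.g. one fixed on the training set), and
#' sensitivity/specificity at that cutoff.
#'
#' @param model a `codel_ensemble`.
#' @param features a labeled [codel_features()].
#' @param cutoff optional fixed cutoff; default derives the Youden cutoff
#'   from these data.
#' @return list with `curve` (a `roc_curve`), `cutoff`, `sensitivity`,
#'   `specificity`, `auc` and the per-sample `scores`.
#' @export
evaluate_model <- function(model, features, cutoff = NULL) {
  y <- features$label
  if (any(is.na(y))) stop("evaluation requires labels for all samples")
  p1 <- forward_proba(model, features)[, "p_codel"]
  curve <- roc_auc(y, p1)
  if (is.null(cutoff)) cutoff <- curve$youden_cutoff
  ss <- sens_spec_at(y, p1, cutoff)
  list(curve = curve, auc = curve$auc, cutoff = cutoff,
       sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
       scores = p1)
}
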