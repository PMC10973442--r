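#' Confusion matrix for the benign/malignant dichotomy
#'
#' Malignant is the positive class: a true positive is a malignant sample
#' predicted malignant, a false negative a malignant sample predicted benign,
#' a true negative a benign sample predicted benign, and a false positive a
#' benign sample predicted malignant.
#'
#' @param y_true,y_pred Character/factor vectors over `{"benign",
#'   "malignant"}`, equal length.
#' @param positive Label of the positive class. Default `"malignant"`.
#' @return A `confusion_matrix` list with counts `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_matrix <- function(y_true, y_pred, positive = "malignant") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    stop("'y_true' and 'y_pred' must be non-empty and of equal length",
         call. = FALSE)
  labs <- unique(c(y_true, y_pred))
  if (length(labs) > 2L)
    stop("more than two distinct labels: ", paste(labs, collapse = ", "),
         call. = FALSE)
  tpos <- y_true == positive; ppos <- y_pred == positive
  structure(list(tp = sum(tpos & ppos), fn = sum(tpos & !ppos),
                 tn = sum(!tpos & !ppos), fp = sum(!tpos & ppos),
                 positive = positive),
            class = "confusion_matrix")
}

#' Build a confusion matrix from raw counts
#' @param tp,fn,tn,fp Non-negative counts.
#' @param positive Positive-class label. Default `"malignant"`.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fn, tn, fp, positive = "malignant") {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(c(as.list(v), list(positive = positive)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion: tp=%d fn=%d tn=%d fp=%d (positive=%s)>\n",
              x$tp, x$fn, x$tn, x$fp, x$positive))
  invisible(x)
}

.undef <- function(metric, denom) {
  stop(structure(class = c("bcicm_undefined_metric", "error", "condition"),
                 list(message = sprintf("%s undefined: denominator %s is zero",
                                        metric, denom),
                      call = NULL)))
}

#' Binary classification metrics (percent)
#'
#' All metrics are percentages in \[0, 100\]:
#' * `accuracy()` = (TP+TN)/(P+N)
#' * `sensitivity()` = TP/(TP+FN), the malignant detection rate
#' * `precision_rate()` = TP/(TP+FP)
#' * `specificity()` = TN/(TN+FP), the benign detection rate
#' * `f1_score()` = harmonic mean of precision and sensitivity
#'
#' A zero denominator raises an error of class `bcicm_undefined_metric`
#' naming the metric.
#'
#' @param cm A [confusion_matrix()] or [confusion_counts()] object.
#' @return A percentage.
#' @name classification_rates
NULL

#' @rdname classification_rates
#' @export
accuracy <- function(cm) {
  tot <- cm$tp + cm$fn + cm$tn + cm$fp
  if (tot == 0) .undef("ACC", "P+N")
  100 * (cm$tp + cm$tn) / tot
}

#' @rdname classification_rates
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0) .undef("SEN", "TP+FN")
  100 * cm$tp / (cm$tp + cm$fn)
}

#' @rdname classification_rates
#' @export
precision_rate <- function(cm) {
  if (cm$tp + cm$fp == 0) .undef("PRE", "TP+FP")
  100 * cm$tp / (cm$tp + cm$fp)
}

#' @rdname classification_rates
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0) .undef("SPE", "TN+FP")
  100 * cm$tn / (cm$tn + cm$fp)
}

#' @rdname classification_rates
#' @export
f1_score <- function(cm) {
  p <- precision_rate(cm); s <- sensitivity(cm)
  if (p + s == 0) .undef("F1", "PRE+SEN")
  2 * p * s / (p + s)
}

#' Full metrics report from a confusion matrix
#'
#' Computes ACC, SEN, PRE, SPE and F1, plus the hard-classifier AUC
#' `(SEN+SPE)/2` — the trapezoidal area under the two-segment ROC through
#' the classifier's single operating point. Metrics with a zero denominator
#' become `NA` with a warning (batch-friendly); use the individual metric
#' functions for strict errors.
#'
#' @param cm A confusion matrix object.
#' @param digits Rounding applied to the report; `NULL` for full precision.
#'   Default `NULL`.
#' @return A `metrics_report`: named list `acc`, `sen`, `pre`, `spe`, `f1`,
#'   `auc`, all percentages.
#' @examples
#' metrics_report(confusion_counts(tp = 90, fn = 10, tn = 93, fp = 7))
#' @export
metrics_report <- function(cm, digits = NULL) {
  grab <- function(f) {
    tryCatch(f(cm), bcicm_undefined_metric = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  out <- list(acc = grab(accuracy), sen = grab(sensitivity),
              pre = grab(precision_rate), spe = grab(specificity),
              f1 = grab(f1_score))
  out$auc <- if (is.na(out$sen) || is.na(out$spe)) NA_real_ else
    (out$sen + out$spe) / 2
  if (!is.null(digits)) out <- lapply(out, round, digits = digits)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %6.3f  SEN %6.3f  PRE %6.3f  SPE %6.3f  F1 %6.3f  AUC %6.3f (%%)\n",
              x$acc, x$sen, x$pre, x$spe, x$f1, x$auc))
  invisible(x)
}

#' Continuous margin score of a point between two class centers
#'
#' Distance to the benign-mapped center minus distance to the
#' malignant-mapped center: positive scores lean malignant and thresholding
#' at 0 reproduces the nearest-center hard assignment.
#'
#' @param points Point matrix (n x D) or single vector.
#' @param benign_center,malignant_center D-vectors.
#' @return Numeric score per point.
#' @export
margin_score <- function(points, benign_center, malignant_center) {
  X <- .as_points(points)
  D <- ncol(X)
  if (length(benign_center) != D || length(malignant_center) != D)
    stop("center dimension does not match points", call. = FALSE)
  db <- sqrt(rowSums((X - matrix(benign_center, nrow(X), D, byrow = TRUE))^2))
  dm <- sqrt(rowSums((X - matrix(malignant_center, nrow(X), D,
                                 byrow = TRUE))^2))
  db - dm
}

#' ROC curve and AUC by threshold sweep
#'
#' Standard ROC: thresholds sweep the observed scores from high to low,
#' predicting malignant when `score >= threshold`; AUC is the trapezoidal
#' area, reported in percent. A single-threshold (hard, 0/1-scored)
#' classifier yields the two-segment curve whose AUC is `(SEN+SPE)/2`.
#'
#' @param scores Numeric scores, higher = more malignant.
#' @param y_true Labels over `{"benign", "malignant"}`.
#' @param positive Positive-class label. Default `"malignant"`.
#' @return A `roc_curve` list: `thresholds`, `fpr`, `tpr` (each including the
#'   (0,0) and (1,1) endpoints) and `auc` in percent.
#' @export
roc_curve <- function(scores, y_true, positive = "malignant") {
  y <- as.character(y_true) == positive
  if (length(scores) != length(y) || length(y) == 0L)
    stop("'scores' and 'y_true' must be non-empty and of equal length",
         call. = FALSE)
  P <- sum(y); N <- sum(!y)
  if (P == 0L || N == 0L)
    .undef("AUC", if (P == 0L) "P" else "N")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y & scores >= t) / P, 0)
  fpr <- vapply(thr, function(t) sum(!y & scores >= t) / N, 0)
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  auc <- 100 * sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr, -Inf), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d points, AUC %.3f%%>\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Align unsupervised cluster indices with class labels
#'
#' An unsupervised two-way clustering has no inherent class identity; of the
#' two possible cluster-to-class mappings, this picks the one maximizing
#' accuracy against the supplied ground truth (ties keep the identity
#' mapping 0 = benign, 1 = malignant).
#'
#' @param clusters Integer vector over `{0, 1}`.
#' @param y_true Labels over `{"benign", "malignant"}`.
#' @return Named character vector `c("0" = ..., "1" = ...)` mapping cluster
#'   index to class label.
#' @export
align_clusters <- function(clusters, y_true) {
  if (length(clusters) != length(y_true) || length(clusters) == 0L)
    stop("'clusters' and 'y_true' must be non-empty and of equal length",
         call. = FALSE)
  if (!all(clusters %in% c(0L, 1L)))
    stop("'clusters' must contain only 0 and 1", call. = FALSE)
  y <- as.character(y_true)
  identity_map <- c("0" = "benign", "1" = "malignant")
  swapped_map  <- c("0" = "malignant", "1" = "benign")
  acc_of <- function(m) mean(m[as.character(clusters)] == y)
  if (acc_of(identity_map) >= acc_of(swapped_map)) identity_map else
    swapped_map
}
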