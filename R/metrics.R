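## Test-set performance battery: AUC (midrank / Mann-Whitney convention),
## ROC points, confusion-matrix metrics at an explicit threshold, the
## Pearson chi-square for 2x2 incidence tables, and prevalence.

check_labels <- function(labels) {
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2])
       else as.integer(labels)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  y
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen case outscores a randomly
#' chosen control, with ties counted 1/2 (midrank convention); equal to
#' the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- check_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (!n1 || !n0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One `(FPR, TPR)` point per distinct score (treating each as the
#' classification threshold "score >= t"), plus the endpoints (0,0) and
#' (1,1). Both coordinates are monotone nondecreasing, and the
#' trapezoidal integral of the curve equals [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return A data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- check_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (!n1 || !n0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y == 1L & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(y == 0L & scores >= t), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

#' Confusion-matrix metrics at a threshold
#'
#' Calls a row positive iff its score is at least `threshold` and reports
#' the standard battery: AUC, sensitivity, specificity, PPV, NPV and
#' classification rate, plus the raw confusion counts. Ratios with an
#' empty denominator (e.g. PPV when nothing is called positive) are
#' reported as `NA` ("N/A"), never as 0.
#'
#' @inheritParams roc_auc
#' @param threshold Score cutoff for a positive call.
#' @return An object of class `"metrics_report"`: a list with `auc`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `classification_rate`
#'   (proportions in `[0, 1]`), `threshold`, and counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @examples
#' confusion_metrics(c(0.6, 0.2, 0.7, 0.1), c(1, 1, 0, 0), 0.5)
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- check_labels(labels)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both classes must be present")
  pos <- scores >= threshold
  tp <- sum(pos & y == 1L); fp <- sum(pos & y == 0L)
  fn <- sum(!pos & y == 1L); tn <- sum(!pos & y == 0L)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    auc = roc_auc(scores, y),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    classification_rate = (tp + tn) / (tp + fp + tn + fn),
    threshold = threshold,
    tp = tp, fp = fp, tn = tn, fn = fn
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "N/A" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("AUC                 %.2f\n", x$auc))
  cat(sprintf("Sensitivity         %s\n", pct(x$sensitivity)))
  cat(sprintf("Specificity         %s\n", pct(x$specificity)))
  cat(sprintf("PPV                 %s\n", pct(x$ppv)))
  cat(sprintf("NPV                 %s\n", pct(x$npv)))
  cat(sprintf("Classification rate %s\n", pct(x$classification_rate)))
  cat(sprintf("(threshold %.4g; tp=%d fp=%d tn=%d fn=%d)\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom: the statistic is
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`.
#'
#' @param table A 2x2 matrix (or object coercible to one) of nonnegative
#'   counts with positive margins.
#' @return A list with `statistic`, `p.value`, and `df = 1`.
#' @examples
#' pearson_chi2(matrix(c(99, 3165, 40, 1373), 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0))
    stop("need a 2x2 table of nonnegative counts")
  r <- rowSums(m); cc <- colSums(m); n <- sum(m)
  if (any(r <= 0) || any(cc <= 0)) stop("all margins must be positive")
  stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (r[1] * r[2] * cc[1] * cc[2])
  list(statistic = unname(stat),
       p.value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Outcome prevalence of a cohort
#'
#' Unweighted case count divided by row count.
#'
#' @param table A cohort data frame with an `outcome` column.
#' @return Proportion in `[0, 1]`.
#' @export
prevalence <- function(table) {
  if (!nrow(table)) stop("prevalence of an empty table is undefined")
  mean(table$outcome == 1L)
}
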