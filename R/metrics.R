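## Classification metrics, ROC/AUC, decision-curve analysis, Mann-Whitney U,
## and cohort summaries.

#' Confusion counts at a score threshold
#'
#' A sample is predicted positive iff its score is greater than or equal to
#' the threshold (ties count as positive).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold (default 0.5).
#' @return Named list `TP`, `FP`, `TN`, `FN`; the four counts partition the
#'   samples.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0 || length(scores) != length(labels))
    stop("scores/labels must be non-empty and equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- scores >= threshold
  list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
       TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP+TN)/N`, `SEN = TP/(TP+FN)`, `SPEC = TN/(TN+FP)`. An undefined
#' ratio (empty class) is reported as `NaN` with a warning.
#'
#' @param counts A list from [confusion_counts()].
#' @return Named numeric vector `ACC`, `SEN`, `SPEC`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    n <- TP + FP + TN + FN
    if (n == 0) stop("no samples")
    if (TP + FN == 0 || TN + FP == 0)
      warning("a class is empty; sensitivity or specificity is NaN")
    c(ACC = (TP + TN) / n,
      SEN = if (TP + FN > 0) TP / (TP + FN) else NaN,
      SPEC = if (TN + FP > 0) TN / (TN + FP) else NaN)
  })
}

#' Area under the ROC curve
#'
#' Trapezoidal ROC area, equal to the tie-corrected probability that a
#' random positive outscores a random negative.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("need 0/1 labels with both classes present")
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

#' ROC curve
#'
#' @param scores,labels As in [auc_score()].
#' @return List of class `"rtn_roc"`: `thresholds`, `fpr`, `tpr` (each
#'   running from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  structure(list(thresholds = r$thresholds[ord],
                 fpr = (1 - r$specificities)[ord],
                 tpr = r$sensitivities[ord],
                 auc = as.numeric(pROC::auc(r))),
            class = "rtn_roc")
}

#' @export
plot.rtn_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "1 - specificity",
                 ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model's predictions across treatment
#' threshold probabilities:
#' `NB(p_t) = TP(p_t)/N - FP(p_t)/N * p_t/(1-p_t)`, where a patient is
#' treated when their predicted probability is at least `p_t`. Also returns
#' the treat-all policy (everyone positive) and the treat-none reference
#' (identically zero).
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels (0/1).
#' @param thresholds Threshold probability grid, strictly inside (0, 1);
#'   default 0.01..0.99 at 0.01 spacing.
#' @return Data frame of class `"rtn_dca"`: `threshold`, `model`, `all`,
#'   `none`.
#' @export
decision_curve <- function(scores, labels, thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0,1)")
  n <- length(labels)
  pos <- sum(labels == 1)
  nb <- vapply(thresholds, function(pt) {
    cc <- confusion_counts(scores, labels, pt)
    cc$TP / n - cc$FP / n * pt / (1 - pt)
  }, numeric(1))
  nb_all <- pos / n - (n - pos) / n * thresholds / (1 - thresholds)
  structure(data.frame(threshold = thresholds, model = nb, all = nb_all,
                       none = 0),
            class = c("rtn_dca", "data.frame"))
}

#' @export
plot.rtn_dca <- function(x, ...) {
  graphics::plot(x$threshold, x$model, type = "l", lwd = 2,
                 xlab = "Threshold probability", ylab = "Net benefit",
                 ylim = range(c(x$model, 0, max(x$all))), ...)
  graphics::lines(x$threshold, x$all, lty = 2)
  graphics::abline(h = 0, lty = 3, col = "grey")
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples: exact enumeration when the
#' smaller sample has at most 8 observations and there are no ties,
#' otherwise the tie-corrected normal approximation.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Aggregate image-level scores to patient level
#'
#' Image-level metrics are the default throughout the package; prognosis,
#' however, is a patient-level question. This helper averages the prediction
#' scores of each patient's images (and carries the patient's label along),
#' ready for patient-level metrics or survival grouping.
#'
#' @param scores Image-level prediction scores.
#' @param patient_id Patient identifier per image.
#' @param labels Optional image-level labels (constant within patient).
#' @return Data frame with one row per patient: `patient_id`, `score`, and
#'   `label` when labels were supplied.
#' @export
patient_scores <- function(scores, patient_id, labels = NULL) {
  if (length(scores) != length(patient_id)) stop("length mismatch")
  s <- tapply(scores, patient_id, mean)
  out <- data.frame(patient_id = names(s), score = as.numeric(s),
                    stringsAsFactors = FALSE)
  if (!is.null(labels))
    out$label <- as.integer(tapply(labels, patient_id, function(x) x[1]))
  out
}
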