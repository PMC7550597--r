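#' Confusion-matrix metrics and ROC/AUC against expert labels
#'
#' Abnormal is the positive class throughout: sensitivity is the recognition
#' rate of expert-abnormal instances, specificity of expert-normal ones.
#' When decision scores are supplied, the ROC curve and its trapezoidal AUC
#' are computed (mid-rank handling of ties), which equals the probability
#' that a randomly chosen abnormal instance scores higher than a randomly
#' chosen normal one. With single-class truth the ROC/AUC are undefined and
#' reported as `NA`.
#'
#' @param predictions Factor/character vector of predicted labels
#'   (normal/abnormal).
#' @param truth Factor/character vector of expert labels, same length.
#' @param scores Optional numeric decision scores (higher = more abnormal).
#' @return Object of class `evaluation_report`: confusion counts `tp`, `fp`,
#'   `tn`, `fn`; `accuracy`, `sensitivity`, `specificity` in percent; `auc`
#'   in [0, 1] and `roc` (data frame `fpr`, `tpr`) when scores are given.
#' @export
evaluate_predictions <- function(predictions, truth, scores = NULL) {
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  p <- factor(as.character(predictions), levels = c("normal", "abnormal"))
  t <- factor(as.character(truth), levels = c("normal", "abnormal"))
  if (anyNA(p) || anyNA(t))
    stop("labels must be 'normal' or 'abnormal' with no missing values")
  tp <- sum(p == "abnormal" & t == "abnormal")
  fp <- sum(p == "abnormal" & t == "normal")
  tn <- sum(p == "normal" & t == "normal")
  fn <- sum(p == "normal" & t == "abnormal")
  n <- length(t)
  rep <- list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    accuracy = 100 * (tp + tn) / n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    auc = NA_real_, roc = NULL)
  if (!is.null(scores)) {
    if (length(scores) != n) stop("scores and truth differ in length")
    if (nlevels(droplevels(t)) == 2) {
      r <- pROC::roc(response = t, predictor = as.numeric(scores),
                     levels = c("normal", "abnormal"), direction = "<",
                     quiet = TRUE)
      rep$auc <- as.numeric(pROC::auc(r))
      rep$roc <- data.frame(fpr = rev(1 - r$specificities),
                            tpr = rev(r$sensitivities))
    } else {
      message("truth contains a single class; ROC/AUC undefined")
    }
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d | TP %d  FP %d  TN %d  FN %d (positive = abnormal)\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  if (!is.na(x$auc)) cat(sprintf("AUC %.3f\n", x$auc))
  invisible(x)
}

#' Plot the ROC curve of an evaluation report
#'
#' @param x An `evaluation_report` computed with scores.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.evaluation_report <- function(x, ...) {
  if (is.null(x$roc)) stop("report has no ROC (no scores were supplied)")
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}
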