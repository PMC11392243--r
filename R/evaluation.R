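# Confusion matrices, the standard detection metrics, ROC/AUC, the
# multi-view label-fusion rule, and max/mean/min fold aggregation.
# Convention throughout: RWMA is the positive class, and metrics are
# reported as percentages at full precision (round only when printing).

confusion_counts <- function(tp, tn, fp, fn, positive = "RWMA") {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, positive = positive),
            class = "ef_confusion")
}

#' Confusion matrix from labels
#'
#' @param truth,predicted Vectors of binary labels (character or factor).
#' @param positive The positive-class label (default `"RWMA"`).
#' @return An `ef_confusion` with TP/TN/FP/FN counts.
#' @export
confusion <- function(truth, predicted, positive = "RWMA") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  tpos <- truth == positive
  ppos <- predicted == positive
  confusion_counts(sum(tpos & ppos), sum(!tpos & !ppos),
                   sum(!tpos & ppos), sum(tpos & !ppos), positive)
}

#' @export
print.ef_confusion <- function(x, ...) {
  cat(sprintf("<confusion> positive = %s: TP %d, TN %d, FP %d, FN %d\n",
              x$positive, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reported as NA", what),
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Detection metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), FPR FP/(FP+TN), specificity TN/(TN+FP),
#' precision TP/(TP+FP), F1 2TP/(2TP+FP+FN) and accuracy
#' (TP+TN)/(TP+TN+FP+FN), all on the percent scale. Metrics with a zero
#' denominator are reported as `NA` with a warning rather than 0.
#'
#' @param cm An `ef_confusion` (or a list with TP/TN/FP/FN).
#' @return Named numeric vector of percentages.
#' @export
metrics <- function(cm) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  c(
    sensitivity = 100 * safe_ratio(tp, tp + fn, "sensitivity"),
    fpr         = 100 * safe_ratio(fp, fp + tn, "FPR"),
    specificity = 100 * safe_ratio(tn, tn + fp, "specificity"),
    precision   = 100 * safe_ratio(tp, tp + fp, "precision"),
    f1          = 100 * safe_ratio(2 * tp, 2 * tp + fp + fn, "F1"),
    accuracy    = 100 * safe_ratio(tp + tn, tp + tn + fp + fn, "accuracy")
  )
}

#' ROC curve and AUC
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, with ties credited 1/2; computed by trapezoidal integration of
#' the ROC curve over all score thresholds (equal scores grouped).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Binary labels.
#' @param positive Positive-class label.
#' @return List with `auc` (fraction in `[0, 1]`) and `curve`
#'   (data.frame of FPR/TPR points from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, truth, positive = "RWMA") {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) stop("scores and labels differ in length")
  pos <- truth == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present for ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  # group tied scores so ties contribute a diagonal ROC step (= 1/2 credit)
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(!y, grp, sum)
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fp) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = unname(auc), curve = data.frame(fpr = unname(fpr), tpr = unname(tpr)))
}

#' Multi-view label fusion
#'
#' Applies the OR rule: a subject is RWMA if either view is labelled MI,
#' non-RWMA only when both views are non-MI.
#'
#' @param a4c,a2c Per-view labels (`"MI"` / `"non-MI"`).
#' @return List with `fused` labels (`"RWMA"`/`"non-RWMA"`) and class
#'   `counts`.
#' @export
fuse_view_labels <- function(a4c, a2c) {
  a4c <- as.character(a4c)
  a2c <- as.character(a2c)
  if (length(a4c) != length(a2c)) stop("view label vectors differ in length")
  ok <- c("MI", "non-MI")
  if (!all(a4c %in% ok) || !all(a2c %in% ok)) {
    stop("view labels must be 'MI' or 'non-MI'")
  }
  fused <- ifelse(a4c == "MI" | a2c == "MI", "RWMA", "non-RWMA")
  list(fused = fused,
       counts = c(RWMA = sum(fused == "RWMA"), `non-RWMA` = sum(fused == "non-RWMA")))
}

#' Aggregate per-fold metric reports
#'
#' @param fold_metrics List of named metric vectors (as from [metrics()]).
#' @return data.frame with one row per metric and max/mean/min columns
#'   (NAs from undefined fold metrics are dropped from the aggregates).
#' @export
aggregate_folds <- function(fold_metrics) {
  if (length(fold_metrics) == 0L) stop("need at least one fold")
  m <- do.call(rbind, fold_metrics)
  agg <- function(f) apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) NA_real_ else f(col)
  })
  data.frame(metric = colnames(m), max = agg(max), mean = agg(mean),
             min = agg(min), row.names = NULL)
}
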