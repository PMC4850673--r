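# Classifier evaluation: confusion counts with an erroneous position as the
# positive class, sensitivity TP/(TP+FN), specificity TN/(TN+FP), the
# Matthews correlation coefficient, and ROC curves built by sweeping the
# threshold on the ERROR confidence.

#' Confusion-matrix metrics for per-position error predictions
#'
#' ERROR is the positive class: an erroneous position detected as such is a
#' TP. MCC is `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined
#' as 0 when any factor of the denominator is 0.
#'
#' @param predicted,truth Vectors of class labels (`"ERROR"`/`"CORRECT"`,
#'   factors or characters, or logicals where `TRUE` means ERROR).
#' @return A one-row tibble with TP, FP, TN, FN, sensitivity, specificity and
#'   mcc.
#' @export
confusion_metrics <- function(predicted, truth) {
  p <- as_error_logical(predicted)
  t <- as_error_logical(truth)
  if (length(p) != length(t)) abort("predicted and truth lengths differ")
  TP <- sum(p & t); FP <- sum(p & !t)
  TN <- sum(!p & !t); FN <- sum(!p & t)
  tibble(TP = TP, FP = FP, TN = TN, FN = FN,
         sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
         specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
         mcc = mcc_from_counts(TP, FP, TN, FN))
}

mcc_from_counts <- function(TP, FP, TN, FN) {
  den <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  if (den == 0) return(0)
  (TP * TN - FP * FN) / den
}

as_error_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  bad <- setdiff(unique(x), c("ERROR", "CORRECT"))
  if (length(bad)) abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  x == "ERROR"
}

#' ROC curve and AUC from ERROR confidences
#'
#' One point per distinct confidence threshold (predict ERROR when the
#' confidence is at least the threshold), from (0,0) to (1,1); AUC by the
#' trapezoidal rule.
#'
#' @param error_confidences Numeric ERROR confidences in `[0, 1]`.
#' @param truth True labels (see [confusion_metrics()]).
#' @return An `iped_roc` object: a tibble with `threshold`, `fpr`, `tpr` and
#'   attribute `auc` (also via [glance()]).
#' @export
roc_curve <- function(error_confidences, truth) {
  t <- as_error_logical(truth)
  if (length(error_confidences) != length(t))
    abort("confidence and truth lengths differ")
  if (all(t) || !any(t)) abort("truth must contain both classes")
  P <- sum(t); N <- sum(!t)
  ord <- order(error_confidences, decreasing = TRUE)
  conf <- error_confidences[ord]
  tt <- t[ord]
  cum_tp <- cumsum(tt)
  cum_fp <- cumsum(!tt)
  last <- !duplicated(conf, fromLast = TRUE)   # last index of each threshold
  pts <- tibble(threshold = conf[last],
                fpr = cum_fp[last] / N,
                tpr = cum_tp[last] / P)
  pts <- bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), pts)
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- bind_rows(pts, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(pts, class = c("iped_roc", class(pts)), auc = auc)
}

#' @export
glance.iped_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_thresholds = nrow(x) - 2L)
}

#' @export
print.iped_roc <- function(x, ...) {
  cat(sprintf("<iped_roc> AUC = %.4f (%d points)\n", attr(x, "auc"), nrow(x)))
  NextMethod()
}

#' Plot a ROC curve
#'
#' @param object An [roc_curve()] result.
#' @param ... Unused.
#' @export
autoplot.iped_roc <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    theme_minimal()
}
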