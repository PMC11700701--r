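# One-vs-rest multiclass ROC analysis with micro- and macro-averaging,
# Youden operating points, and confusion-table metrics.

# Binary ROC from scores: points at every distinct score threshold,
# prepended with (0, 0). Trapezoidal AUC.
binary_roc <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]
  positive <- positive[ord]
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop2("ROC needs at least one positive and one negative")
  keep <- c(diff(score) != 0, TRUE) # last index of each distinct score
  tpr <- c(0, cumsum(positive)[keep] / n_pos)
  fpr <- c(0, cumsum(!positive)[keep] / n_neg)
  thr <- c(Inf, score[keep])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc)
}

#' One-vs-rest multiclass ROC analysis
#'
#' Builds a per-class ROC curve (class posterior as the score, trapezoidal
#' AUC), the micro-average curve from the pooled binarized label/score
#' pairs, and the macro-average curve by averaging per-class TPR over a
#' common 101-point FPR grid with linear interpolation. The macro AUC is
#' the unweighted mean of the per-class AUCs; `macro$auc_grid` is the
#' trapezoidal AUC of the grid-averaged curve.
#'
#' @param posterior Items x classes matrix of scores (class posteriors;
#'   rows sum to ~1).
#' @param labels True class labels, one per row.
#' @param fpr_grid FPR grid for macro averaging, default
#'   `seq(0, 1, length.out = 101)`.
#' @return An object of class `"roc_result"`: `per_class` (list of curves
#'   with AUC), `micro`, `macro`, `auc` (named vector of all AUCs).
#' @export
roc_one_vs_rest <- function(posterior, labels,
                            fpr_grid = seq(0, 1, length.out = 101)) {
  posterior <- as.matrix(posterior)
  labels <- as.character(labels)
  classes <- colnames(posterior)
  if (is.null(classes)) stop2("posterior matrix needs class column names")
  present <- classes[classes %in% labels & vapply(classes, function(cl)
    sum(labels != cl) > 0, logical(1))]
  skipped <- setdiff(classes, present)
  if (length(skipped))
    warning(sprintf("classes absent from labels skipped: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  per_class <- lapply(present, function(cl)
    binary_roc(posterior[, cl], labels == cl))
  names(per_class) <- present
  bin <- vapply(present, function(cl) labels == cl, logical(length(labels)))
  micro <- binary_roc(as.vector(posterior[, present, drop = FALSE]),
                      as.vector(bin))
  tpr_interp <- vapply(per_class, function(r)
    stats::approx(r$fpr, r$tpr, xout = fpr_grid, method = "linear",
                  ties = max, rule = 2)$y,
    numeric(length(fpr_grid)))
  macro_tpr <- rowMeans(tpr_interp)
  macro <- list(
    fpr = fpr_grid, tpr = macro_tpr,
    auc = mean(vapply(per_class, `[[`, numeric(1), "auc")),
    auc_grid = sum(diff(fpr_grid) *
                     (macro_tpr[-1] + macro_tpr[-length(macro_tpr)]) / 2))
  aucs <- c(vapply(per_class, `[[`, numeric(1), "auc"),
            micro = micro$auc, macro = macro$auc)
  structure(list(per_class = per_class, micro = micro, macro = macro,
                 auc = aucs, fpr_grid = fpr_grid),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("One-vs-rest ROC analysis\n")
  for (nm in names(x$per_class))
    cat(sprintf("  %-10s AUC = %.3f\n", nm, x$per_class[[nm]]$auc))
  cat(sprintf("  micro-average AUC = %.3f\n", x$micro$auc))
  cat(sprintf("  macro-average AUC = %.3f\n", x$macro$auc))
  invisible(x)
}

#' Youden operating point on a ROC curve
#'
#' Maximizes Youden's J = TPR - FPR over the curve's points; ties are
#' broken toward higher specificity (lower FPR). When every score is
#' identical the curve is the diagonal, J = 0 everywhere, and the result
#' carries `degenerate = TRUE`.
#'
#' @param curve A single-class curve from [roc_one_vs_rest()] (list with
#'   `fpr`, `tpr`, `thresholds`).
#' @param method Operating-point criterion; only `"youden"`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`,
#'   `degenerate`.
#' @export
choose_threshold <- function(curve, method = c("youden")) {
  method <- match.arg(method)
  j <- curve$tpr - curve$fpr
  best <- order(-j, curve$fpr)[1L]
  list(threshold = curve$thresholds[best],
       sensitivity = curve$tpr[best],
       specificity = 1 - curve$fpr[best],
       j = j[best],
       degenerate = all(abs(j) < 1e-12))
}

#' One-vs-rest confusion-table metrics
#'
#' Per class: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' and F1, with a macro (unweighted mean) row appended.
#'
#' @param pred Predicted labels.
#' @param labels True labels.
#' @param levels Optional class vocabulary (defaults to the labels seen).
#' @return Data frame with one row per class plus a `"macro"` row.
#' @export
confusion_metrics <- function(pred, labels, levels = NULL) {
  pred <- as.character(pred)
  labels <- as.character(labels)
  if (length(pred) == 0L) stop2("empty input")
  if (length(pred) != length(labels)) stop2("length mismatch")
  if (is.null(levels)) {
    levels <- intersect(subtype_levels(), unique(c(labels, pred)))
    if (length(levels) == 0L) levels <- sort(unique(c(labels, pred)))
  }
  rows <- lapply(levels, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    tn <- sum(pred != cl & labels != cl)
    data.frame(class = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               accuracy = (tp + tn) / length(pred),
               f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
                    else NA_real_)
  })
  out <- do.call(rbind, rows)
  macro <- data.frame(class = "macro",
                      sensitivity = mean(out$sensitivity, na.rm = TRUE),
                      specificity = mean(out$specificity, na.rm = TRUE),
                      accuracy = mean(pred == labels),
                      f1 = mean(out$f1, na.rm = TRUE))
  rbind(out, macro)
}
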