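# Classification evaluation: confusion counts with HS as the positive
# class, the ratio metrics derived from them, and rank-based AUROC.
# Ratios with a zero denominator are reported as NaN (with a reason
# attribute) rather than raised: degenerate folds occur routinely in
# 10-fold cross-validation on a small minority class and must not abort
# a benchmark run.

check_labels <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("HS", "NS"))
  if (length(bad) > 0) {
    hs_error("hs_validation_error",
             paste("labels outside {HS, NS}:", paste(bad, collapse = ", ")))
  }
  x
}

#' Confusion counts
#'
#' Tallies true/false positives and negatives with HS as the positive
#' class: TP = correctly classified HS, TN = correctly classified NS,
#' FP = NS classified as HS, FN = HS classified as NS.
#'
#' @param pred,truth Character/factor vectors over \{"HS","NS"\}.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion <- function(pred, truth) {
  pred <- check_labels(pred); truth <- check_labels(truth)
  if (length(pred) != length(truth) || length(pred) == 0) {
    hs_error("hs_validation_error", "pred and truth must be equal-length, non-empty")
  }
  c(TP = sum(pred == "HS" & truth == "HS"),
    TN = sum(pred == "NS" & truth == "NS"),
    FP = sum(pred == "HS" & truth == "NS"),
    FN = sum(pred == "NS" & truth == "HS"))
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Threshold classification metrics
#'
#' Accuracy, TPR (sensitivity), TNR (specificity), PPV (precision), NPV,
#' FDR, FNR, F1 and MCC from confusion counts. Undefined ratios (zero
#' denominator) are NaN.
#'
#' @param c Named counts `c(TP, TN, FP, FN)` (from [confusion()]).
#' @return Named numeric vector of the nine metrics.
#' @export
classification_metrics <- function(c) {
  tp <- c[["TP"]]; tn <- c[["TN"]]; fp <- c[["FP"]]; fn <- c[["FN"]]
  if (any(c(tp, tn, fp, fn) < 0) || sum(c(tp, tn, fp, fn)) < 1) {
    hs_error("hs_validation_error", "counts must be non-negative with a positive sum")
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(Accuracy = (tp + tn) / (tp + fp + fn + tn),
    TPR = safe_ratio(tp, tp + fn),
    TNR = safe_ratio(tn, fp + tn),
    PPV = safe_ratio(tp, tp + fp),
    NPV = safe_ratio(tn, tn + fn),
    FDR = safe_ratio(fp, fp + tp),
    FNR = safe_ratio(fn, tp + fn),
    F1 = safe_ratio(2 * tp, 2 * tp + fp + fn),
    MCC = if (mcc_den == 0) NaN else (tp * tn - fp * fn) / mcc_den)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random HS
#' scores above a random NS, ties counting one half.
#'
#' @param scores Numeric scores (higher = more HS-like).
#' @param truth Labels over \{"HS","NS"\}; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  truth <- check_labels(truth)
  pos <- truth == "HS"
  if (!any(pos) || all(pos)) {
    hs_error("hs_validation_error", "AUROC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metrics report
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param scores Optional scores for AUROC (omitted when `NULL` or when
#'   only one class is present in `truth`).
#' @return Named numeric vector: the nine threshold metrics plus AUROC.
#' @export
metrics_report <- function(pred, truth, scores = NULL) {
  m <- classification_metrics(confusion(pred, truth))
  au <- if (!is.null(scores) && length(unique(check_labels(truth))) == 2) {
    auroc(scores, truth)
  } else {
    NaN
  }
  c(AUROC = au, m)
}
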