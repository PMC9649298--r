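# FOV-masked pixel classification metrics.
#
# Every pixel inside the field-of-view mask is classed vessel (positive) or
# background (negative); from the TP/TN/FP/FN tallies:
#   ACC = (TP + TN) / (TN + FP + TP + FN)
#   SE  = TP / (TP + FN)
#   SP  = TN / (TN + FP)
# plus F1 = 2TP / (2TP + FP + FN) and the trapezoid area under the ROC curve
# swept over the unique prediction scores (equal to the pairwise ranking
# probability P(score_pos > score_neg) + 0.5 P(tie)).

check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1)))
    stop(sprintf("%s must be strictly binary (0/1)", what), call. = FALSE)
  invisible(x)
}

#' Confusion counts over the field of view
#'
#' @param pred,truth Binary (0/1) arrays of identical shape; vessel = 1.
#' @param fov Binary mask of the same shape; only `fov == 1` pixels are
#'   evaluated. Defaults to all pixels.
#' @return A `confusion_counts` object with integer fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  if (is.null(fov)) {
    fov <- rep(1, length(pred))
    dim(fov) <- dim(pred)
  }
  if (!identical(dim(pred), dim(truth)) || !identical(dim(pred), dim(fov)))
    stop("pred, truth and fov must have identical shapes", call. = FALSE)
  check_binary(pred, "pred"); check_binary(truth, "truth"); check_binary(fov, "fov")
  keep <- fov == 1
  p <- pred[keep]; t <- truth[keep]
  structure(list(TP = sum(p == 1 & t == 1), TN = sum(p == 0 & t == 0),
                 FP = sum(p == 1 & t == 0), FN = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(c)))
  structure(c[c("TP", "TN", "FP", "FN")], class = "confusion_counts")
}

safe_ratio <- function(num, den) {
  if (den == 0) {
    warning("degenerate confusion counts: zero denominator, returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Pixel classification metrics from confusion counts
#'
#' Zero denominators (degenerate images) yield 0 with a warning rather than
#' an error.
#'
#' @param c A `confusion_counts` object (or a named list with TP/TN/FP/FN).
#' @return A numeric scalar in \[0, 1\].
#' @export
accuracy <- function(c) {
  c <- as_counts(c)
  safe_ratio(c$TP + c$TN, c$TN + c$FP + c$TP + c$FN)
}

#' @rdname accuracy
#' @export
sensitivity <- function(c) { c <- as_counts(c); safe_ratio(c$TP, c$TP + c$FN) }

#' @rdname accuracy
#' @export
specificity <- function(c) { c <- as_counts(c); safe_ratio(c$TN, c$TN + c$FP) }

#' @rdname accuracy
#' @export
f1_score <- function(c) { c <- as_counts(c); safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN) }

#' ROC curve and AUC over the field of view
#'
#' Sweeps the decision threshold over the unique prediction scores and
#' integrates the curve by the trapezoid rule; for finite scores this equals
#' the pairwise ranking statistic `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Numeric array of prediction scores (finite).
#' @param truth Binary array of the same shape.
#' @param fov Optional binary mask restricting evaluation.
#' @return List with `curve` (data.frame of `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc` (numeric scalar).
#' @export
roc_auc <- function(scores, truth, fov = NULL) {
  if (is.null(fov)) {
    fov <- rep(1, length(scores))
    dim(fov) <- dim(scores)
  }
  if (!identical(dim(scores), dim(truth)) || !identical(dim(scores), dim(fov)))
    stop("scores, truth and fov must have identical shapes", call. = FALSE)
  check_binary(truth, "truth"); check_binary(fov, "fov")
  keep <- fov == 1
  s <- scores[keep]; t <- truth[keep]
  if (!all(is.finite(s))) stop("scores must be finite", call. = FALSE)
  P <- sum(t == 1); N <- sum(t == 0)
  if (P == 0 || N == 0)
    stop("AUC undefined: truth contains a single class inside the FOV", call. = FALSE)
  o <- order(s, decreasing = TRUE)
  s <- s[o]; t <- t[o]
  # group tied scores so each unique threshold contributes one curve point
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t); fp <- cumsum(1 - t)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / P, 1)
  fpr <- c(0, fp[last] / N, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' All segmentation metrics for one prediction
#'
#' @param scores Numeric probability array.
#' @param truth,fov Binary arrays (see [confusion_counts()]).
#' @param threshold Binarisation threshold for ACC/SE/SP/F1 (default 0.5).
#' @return One-row data.frame with columns `ACC`, `SEN`, `SP`, `AUC`, `F1`.
#' @export
segmentation_metrics <- function(scores, truth, fov = NULL, threshold = 0.5) {
  pred <- (scores >= threshold) * 1
  dim(pred) <- dim(scores)
  cc <- confusion_counts(pred, truth, fov)
  auc <- tryCatch(roc_auc(scores, truth, fov)$auc, error = function(e) NA_real_)
  data.frame(ACC = accuracy(cc), SEN = sensitivity(cc), SP = specificity(cc),
             AUC = auc, F1 = f1_score(cc))
}

#' Write a metrics report
#'
#' Emits the per-dataset metric table (columns ACC, SEN, SP, AUC, F1) as CSV
#' and as aligned text.
#'
#' @param tab data.frame with a `dataset` column plus the metric columns.
#' @param csv,txt Output paths (either may be `NULL` to skip).
#' @return `tab`, invisibly.
#' @export
write_metrics_report <- function(tab, csv = NULL, txt = NULL) {
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(txt)) {
    fmt <- tab
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(x) sprintf("%.4f", x))
    writeLines(capture.output(print(fmt, row.names = FALSE)), txt)
  }
  invisible(tab)
}
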