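#' Confusion counts for a binary classifier
#'
#' @param pred_labels predicted labels.
#' @param true_labels reference labels; must contain at most two distinct
#'   values jointly with `pred_labels`.
#' @param positive the positive-class label (e.g. `"ES"`).
#' @return named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion <- function(pred_labels, true_labels, positive = "ES") {
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  if (length(pred_labels) != length(true_labels))
    stop("pred_labels and true_labels differ in length")
  labs <- union(unique(pred_labels), unique(true_labels))
  if (length(labs) > 2)
    stop("labels are not binary: ", paste(labs, collapse = ", "))
  if (!positive %in% labs)
    stop("positive label '", positive, "' absent from the data")
  pp <- pred_labels == positive
  tp <- true_labels == positive
  c(tp = sum(pp & tp), tn = sum(!pp & !tp),
    fp = sum(pp & !tp), fn = sum(!pp & tp))
}

.rate_pct <- function(num, den) {
  if (den == 0) return(NA_real_)  # undefined, not 0
  100 * num / den
}

#' Accuracy, specificity and sensitivity (percent)
#'
#' * accuracy = (TP + TN) / (TP + TN + FP + FN)
#' * specificity = TN / (TN + FP)
#' * sensitivity (= TPR, recall) = TP / (TP + FN)
#'
#' Values are returned in percent at full precision; use
#' [report_percent()] for the conventional one-decimal reporting. A metric
#' whose denominator is zero is returned as `NA` (undefined), never as 0.
#'
#' @param c named counts from [confusion()] (`tp`, `tn`, `fp`, `fn`).
#' @return numeric percent in `[0, 100]`, or `NA` if undefined.
#' @export
accuracy <- function(c) {
  .rate_pct(c[["tp"]] + c[["tn"]], sum(c[c("tp", "tn", "fp", "fn")]))
}

#' @rdname accuracy
#' @export
specificity <- function(c) .rate_pct(c[["tn"]], c[["tn"]] + c[["fp"]])

#' @rdname accuracy
#' @export
sensitivity <- function(c) .rate_pct(c[["tp"]], c[["tp"]] + c[["fn"]])

#' Round a percentage half-up to one decimal (reporting convention)
#'
#' Base R's `round()` rounds half to even; published tables conventionally
#' round half up, so 94.15 reports as 94.2.
#'
#' @param x numeric percent.
#' @param digits decimals to keep.
#' @return rounded numeric.
#' @export
report_percent <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' ROC curve by threshold sweep
#'
#' Sorts instances by decreasing score and emits one `(fpr, tpr)` point per
#' distinct score value (tied scores collapse into a single step), plus the
#' `(0, 0)` endpoint. With both classes present the curve ends at `(1, 1)`.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param true_labels reference labels.
#' @param positive positive-class label.
#' @return a data.frame of class `roc_curve` with columns `threshold`,
#'   `fpr`, `tpr` (first row is the `(0, 0)` endpoint with threshold `Inf`).
#' @export
roc_curve <- function(scores, true_labels, positive = "ES") {
  stopifnot(length(scores) == length(true_labels))
  if (any(!is.finite(scores))) stop("scores must be finite")
  truth <- as.character(true_labels) == positive
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  cum_tp <- cumsum(t)
  cum_fp <- cumsum(!t)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  out <- data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, cum_fp[last_of_tie] / n_neg),
    tpr = c(0, cum_tp[last_of_tie] / n_pos)
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' Trapezoidal area under a ROC curve
#'
#' Equals the Mann-Whitney concordance probability, with ties between a
#' positive and a negative score receiving half credit (the trapezoid over
#' a tie step).
#'
#' @param curve a [roc_curve()] data.frame.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(all(c("fpr", "tpr") %in% names(curve)))
  fpr <- curve$fpr
  tpr <- curve$tpr
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' All evaluation metrics for one prediction set
#'
#' Convenience wrapper producing the confusion counts, the three percent
#' metrics and (when scores are given) the ROC curve and AUC.
#'
#' @param pred_labels,true_labels label vectors.
#' @param scores optional positive-class scores for ROC/AUC.
#' @param positive positive-class label.
#' @return a list with `confusion`, `accuracy`, `specificity`,
#'   `sensitivity` (full-precision percents) and, with scores, `roc`
#'   and `auc`.
#' @export
classification_metrics <- function(pred_labels, true_labels, scores = NULL,
                                   positive = "ES") {
  cc <- confusion(pred_labels, true_labels, positive)
  out <- list(confusion = cc,
              accuracy = accuracy(cc),
              specificity = specificity(cc),
              sensitivity = sensitivity(cc))
  if (!is.null(scores)) {
    out$roc <- roc_curve(scores, true_labels, positive)
    out$auc <- auc(out$roc)
  }
  out
}
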