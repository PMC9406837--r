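#' Two-class confusion matrix
#'
#' Tallies TP/FP/FN/TN with malignant as the positive class: TP are
#' malignant images classified malignant, TN normal classified normal, FP
#' normal classified malignant, FN malignant classified normal.
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @param positive Positive class label (default `"malignant"` when
#'   present, else the lexicographically second label).
#' @return A `confusion_2x2` list with integer fields `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion <- function(y_true, y_pred, positive = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  lev <- sort(unique(c(y_true, y_pred)))
  if (length(lev) > 2L) stop("labels are not binary: ", paste(lev, collapse = ", "))
  if (is.null(positive))
    positive <- if ("malignant" %in% lev) "malignant" else lev[length(lev)]
  structure(list(
    TP = sum(y_true == positive & y_pred == positive),
    FP = sum(y_true != positive & y_pred == positive),
    FN = sum(y_true == positive & y_pred != positive),
    TN = sum(y_true != positive & y_pred != positive),
    positive = positive
  ), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(true = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  cat("Confusion matrix (positive = ", x$positive, "):\n", sep = "")
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix metric panel
#'
#' Accuracy (TP+TN over all), specificity (TN over TN+FP), sensitivity
#' (TP over TP+FN) and precision (TP over TP+FP), each as a percentage.
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never as 0. Also reports `auc_ratio`, the sensitivity/specificity ratio
#' (see [auc_ratio()]).
#'
#' @param cm A `confusion_2x2`.
#' @return A `metrics_report` list with fields `accuracy`, `specificity`,
#'   `sensitivity`, `precision` (percent) and `auc_ratio`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_2x2"))
  acc <- safe_ratio(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN) * 100
  spec <- safe_ratio(cm$TN, cm$TN + cm$FP) * 100
  sens <- safe_ratio(cm$TP, cm$TP + cm$FN) * 100
  prec <- safe_ratio(cm$TP, cm$TP + cm$FP) * 100
  structure(list(accuracy = acc, specificity = spec, sensitivity = sens,
                 precision = prec,
                 auc_ratio = if (is.na(spec) || spec == 0) NA_real_
                             else sens / spec),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in c("accuracy", "specificity", "sensitivity", "precision")) {
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.1f %%", x[[nm]])))
  }
  cat(sprintf("  %-12s %s\n", "auc_ratio",
              if (is.na(x$auc_ratio)) "undefined" else sprintf("%.3f", x$auc_ratio)))
  if (!is.null(x$roc_auc))
    cat(sprintf("  %-12s %.1f %%\n", "roc_auc", x$roc_auc))
  invisible(x)
}

#' Sensitivity/specificity ratio
#'
#' The ratio sensitivity over specificity. Note this is not the standard
#' area under the ROC curve; it is reported alongside [roc_auc()], which
#' is the trapezoidal ROC area and is the quantity used in the headline
#' panel. Undefined when specificity is zero.
#'
#' @param cm A `confusion_2x2`.
#' @return A single number (or `NA` when undefined).
#' @export
auc_ratio <- function(cm) metrics(cm)$auc_ratio

#' Trapezoidal ROC AUC
#'
#' Area under the true-positive-rate vs false-positive-rate curve computed
#' by the trapezoidal rule (via pROC), as a percentage. Invariant under
#' strictly monotone transforms of the scores; 100 when every positive is
#' ranked above every negative, about 50 for label-independent scores.
#'
#' @param y_true Binary labels.
#' @param scores Real-valued positive-class scores.
#' @param positive Positive class label.
#' @return AUC in percent.
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  lev <- sort(unique(y_true))
  if (is.null(positive))
    positive <- if ("malignant" %in% lev) "malignant" else lev[length(lev)]
  negative <- setdiff(lev, positive)
  r <- pROC::roc(response = factor(y_true, levels = c(negative, positive)),
                 predictor = as.numeric(scores),
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r)) * 100
}

#' Error histogram
#'
#' Histogram of the per-sample errors `targets - outputs` over `n_bins`
#' equal-width bins spanning the observed error range, the standard
#' training-diagnostic view of a network's residuals.
#'
#' @param targets,outputs Equal-length numeric vectors (e.g. 0/1 targets
#'   and positive-class probabilities).
#' @param n_bins Number of bins (default 20).
#' @return List with `edges` (length `n_bins + 1`), `mids` and `counts`.
#' @export
error_histogram <- function(targets, outputs, n_bins = 20L) {
  if (length(targets) == 0L) stop("empty input")
  if (length(targets) != length(outputs))
    stop("targets and outputs lengths differ")
  err <- targets - outputs
  lo <- min(err); hi <- max(err)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(err, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  list(edges = edges, mids = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
       counts = tabulate(bin, nbins = n_bins))
}
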