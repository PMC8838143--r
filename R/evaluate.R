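#' @include train.R
NULL

#' Confusion counts with MEL as the positive class
#'
#' @param predicted,truth equal-length character vectors over
#'   \code{\{MEL, BEN\}}.
#' @return named integer vector \code{TP, FP, TN, FN}.
#' @export
confusionCounts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length")
  stopifnot(all(predicted %in% LABEL_LEVELS), all(truth %in% LABEL_LEVELS))
  c(TP = sum(predicted == "MEL" & truth == "MEL"),
    FP = sum(predicted == "MEL" & truth == "BEN"),
    TN = sum(predicted == "BEN" & truth == "BEN"),
    FN = sum(predicted == "BEN" & truth == "MEL"))
}

safe_ratio <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from the
#' four confusion counts:
#' \deqn{ACC = \frac{TP + TN}{TP + FP + TN + FN}, \quad
#'  PRE = \frac{TP}{TP + FP}, \quad REC = \frac{TP}{TP + FN},}
#' \deqn{SPE = \frac{TN}{TN + FP}, \quad F1 = \frac{2TP}{2TP + FP + FN}.}
#' Zero-denominator cases yield 0 and set the \code{degenerate} flag.
#'
#' @param counts named integer vector \code{TP, FP, TN, FN} (at least one
#'   sample).
#' @param auc optional AUC to carry into the report.
#' @param rocPoints optional ROC curve data.frame (FPR, TPR).
#' @return an \linkS4class{EvalReport}.
#' @export
evalMetrics <- function(counts, auc = NA_real_,
                        rocPoints = data.frame(FPR = numeric(),
                                               TPR = numeric())) {
  counts <- as.integer(counts[c("TP", "FP", "TN", "FN")])
  names(counts) <- c("TP", "FP", "TN", "FN")
  if (any(is.na(counts))) stop("counts must be named TP, FP, TN, FN")
  if (sum(counts) == 0L) stop("at least one evaluated sample is required")
  tp <- counts["TP"]; fp <- counts["FP"]; tn <- counts["TN"]; fn <- counts["FN"]
  vals <- rbind(ACC = safe_ratio(tp + tn, sum(counts)),
                PRE = safe_ratio(tp, tp + fp),
                REC = safe_ratio(tp, tp + fn),
                SPE = safe_ratio(tn, tn + fp),
                F1  = safe_ratio(2 * tp, 2 * tp + fp + fn))
  new("EvalReport", counts = counts,
      metrics = setNames(vals[, 1], rownames(vals)),
      auc = auc, rocPoints = rocPoints,
      degenerate = any(vals[, 2] == 1))
}

#' ROC curve and AUC from MEL scores
#'
#' Threshold sweep over the unique scores: each threshold yields one
#' (FPR, TPR) point and the area under the piecewise-linear curve is
#' computed by the trapezoidal rule. The result equals the Mann-Whitney
#' statistic: the fraction of (positive, negative) pairs ranked concordantly,
#' ties counted one half.
#'
#' @param scores numeric MEL probability (or any monotone score) per sample.
#' @param truth character labels over \code{\{MEL, BEN\}}; both classes must
#'   be present.
#' @return list with \code{auc} and \code{rocPoints} (data.frame FPR, TPR,
#'   monotone in FPR).
#' @export
rocAuc <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("scores and truth must have the same length")
  pos <- truth == "MEL"
  if (!any(pos) || all(pos))
    stop("both classes must be present to compute a ROC curve")
  # descending threshold sweep
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(ths, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc, rocPoints = data.frame(FPR = fpr, TPR = tpr))
}

#' Evaluate a model on labelled images
#'
#' Predicts class probabilities, derives labels (ties toward BEN), and
#' assembles confusion counts, the five metrics and ROC/AUC into one report.
#'
#' @param model an \linkS4class{LCNetModel}.
#' @param images list of 128 x 128 x 3 arrays (0..255 scale).
#' @param truth character labels aligned with \code{images}.
#' @param batchSize forward-pass batch size.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(model, images, truth, batchSize = 32L) {
  probs <- predictProb(model, images, batchSize = batchSize)
  pred <- predictLabel(probs)
  counts <- confusionCounts(pred, truth)
  if (length(unique(truth)) == 2L) {
    roc <- rocAuc(probs[, "MEL"], truth)
    evalMetrics(counts, auc = roc$auc, rocPoints = roc$rocPoints)
  } else {
    evalMetrics(counts)
  }
}

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (MEL positive)\n")
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n",
              object@counts["TP"], object@counts["FP"],
              object@counts["TN"], object@counts["FN"]))
  cat(sprintf("  ACC=%.4f PRE=%.4f REC=%.4f SPE=%.4f F1=%.4f AUC=%s\n",
              object@metrics["ACC"], object@metrics["PRE"],
              object@metrics["REC"], object@metrics["SPE"],
              object@metrics["F1"],
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc))))
  if (object@degenerate)
    cat("  note: one or more metrics had a zero denominator (reported as 0)\n")
  invisible(object)
})

#' Write an evaluation report as JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(
    list(counts = as.list(report@counts),
         metrics = as.list(report@metrics),
         auc = report@auc,
         degenerate = report@degenerate,
         roc_points = report@rocPoints),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
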