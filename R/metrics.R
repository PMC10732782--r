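#' Confusion matrix at a probability threshold
#'
#' Calls a site positive when its score is strictly greater than the
#' threshold, and tabulates TP/FP/FN/TN against the truth labels.
#'
#' @param scores numeric probability vector.
#' @param truth binary vector (1 = positive) of the same length.
#' @param threshold probability cutoff (default 0.5).
#' @return list of class `"ConfusionMatrix"` with elements `TP`, `FP`,
#'   `FN`, `TN`, `threshold`.
#' @export
confusionMatrix <- function(scores, truth, threshold = 0.5) {
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  call_pos <- scores > threshold
  truth <- as.integer(truth)
  structure(list(TP = sum(call_pos & truth == 1),
                 FP = sum(call_pos & truth == 0),
                 FN = sum(!call_pos & truth == 1),
                 TN = sum(!call_pos & truth == 0),
                 threshold = threshold),
            class = "ConfusionMatrix")
}

#' Build a confusion matrix directly from counts
#'
#' Convenience constructor for working with published count tables.
#'
#' @param TP,FP,FN,TN non-negative counts.
#' @param threshold the cutoff the counts were produced at (default 0.5).
#' @return list of class `"ConfusionMatrix"`.
#' @export
confusionFromCounts <- function(TP, FP, FN, TN = 0, threshold = 0.5) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, threshold = threshold),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat("Confusion matrix (threshold ", x$threshold, ")\n", sep = "")
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              call = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`.  Degenerate
#' denominators yield 0 with a warning rather than an error.
#'
#' @param cm a `"ConfusionMatrix"`.
#' @return named numeric vector `c(P=, R=, F1=)` at full precision.
#' @export
prf <- function(cm) {
  P <- if (cm$TP + cm$FP > 0) cm$TP / (cm$TP + cm$FP) else {
    warning("no positive calls; precision defined as 0"); 0
  }
  R <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else {
    warning("no positive truth; recall defined as 0"); 0
  }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

#' F-beta score
#'
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)`: the harmonic-style mean
#' that treats recall as beta times as important as precision.  `beta = 1`
#' reduces to F1; the limits are recall as `beta` grows and precision as
#' `beta` shrinks.
#'
#' @param P,R precision and recall in \[0, 1\].
#' @param beta positive weight.
#' @return the F-beta score (0 when the numerator is 0).
#' @export
fbeta <- function(P, R, beta) {
  stopifnot(beta > 0, P >= 0, P <= 1, R >= 0, R <= 1)
  num <- (1 + beta^2) * P * R
  if (num == 0) return(0)
  num / (beta^2 * P + R)
}

#' F-beta sweep over a grid
#'
#' @param cm a `"ConfusionMatrix"`.
#' @param betaGrid strictly increasing positive grid (default 0.1..3.0 by
#'   0.1).
#' @return `data.frame` with columns `beta`, `fbeta`.
#' @export
fbetaCurve <- function(cm, betaGrid = seq(0.1, 3.0, by = 0.1)) {
  stopifnot(all(betaGrid > 0), !is.unsorted(betaGrid, strictly = TRUE))
  pr <- prf(cm)
  data.frame(beta = betaGrid,
             fbeta = vapply(betaGrid, function(b) fbeta(pr["P"], pr["R"], b),
                            numeric(1)))
}

#' Smallest beta at which one method's F-beta reaches another's
#'
#' Sweeps the grid and returns the smallest beta where method A's F-beta is
#' greater than or equal to method B's ("reaches" counts ties).
#'
#' @param cmA,cmB confusion matrices for the two methods.
#' @param betaGrid strictly increasing positive grid (default 0.1..3.0 by
#'   0.1).
#' @return the crossover beta, or `NA` if A never reaches B on the grid.
#' @export
fbetaCrossover <- function(cmA, cmB, betaGrid = seq(0.1, 3.0, by = 0.1)) {
  a <- fbetaCurve(cmA, betaGrid)$fbeta
  b <- fbetaCurve(cmB, betaGrid)$fbeta
  hit <- which(a >= b)
  if (!length(hit)) return(NA_real_)
  betaGrid[hit[1]]
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps all unique scores as thresholds (ties grouped, so tied scores
#' enter or leave the positive call set together).  The ROC area uses the
#' trapezoidal rule; the precision-recall area uses the step-wise
#' (rectangular) rule `sum((R_i - R_{i-1}) * P_i)`, which avoids the
#' optimistic bias of linear PR interpolation (`interpolate = "linear"`
#' switches to trapezoids).
#'
#' @param scores numeric score vector.
#' @param truth binary truth vector; both classes must be present.
#' @param interpolate `"step"` (default) or `"linear"` PR integration.
#' @return list with `roc` (`data.frame` threshold/FPR/TPR), `pr`
#'   (`data.frame` threshold/recall/precision), `auroc`, `auprc`, and
#'   `thresholdTable` (threshold, TPR, FPR).
#' @export
rocPr <- function(scores, truth, interpolate = c("step", "linear")) {
  interpolate <- match.arg(interpolate)
  truth <- as.integer(truth)
  nP <- sum(truth == 1); nN <- sum(truth == 0)
  if (nP == 0 || nN == 0)
    stop("both classes must be present to compute ROC/PR curves")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last <- !duplicated(s, fromLast = TRUE) # last index of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  thr <- s[last]
  tpr <- c(0, tp / nP)
  fpr <- c(0, fp / nN)
  prec <- c(1, tp / (tp + fp))
  rec <- tpr
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (interpolate == "step") {
    auprc <- sum(diff(rec) * utils::tail(prec, -1))
  } else {
    auprc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  }
  list(roc = data.frame(threshold = c(Inf, thr), FPR = fpr, TPR = tpr),
       pr = data.frame(threshold = c(Inf, thr), recall = rec,
                       precision = prec),
       auroc = auroc, auprc = auprc,
       thresholdTable = data.frame(threshold = thr, TPR = tpr[-1],
                                   FPR = fpr[-1]))
}

#' Full evaluation report for a score vector
#'
#' Bundles the confusion matrix at the given threshold, precision / recall /
#' F1, the F-beta sweep and the ROC / PR curves with their areas.
#'
#' @param scores probability vector.
#' @param truth binary truth vector.
#' @param threshold hard-call cutoff (default 0.5).
#' @param betaGrid F-beta grid (default 0.1..3.0 by 0.1).
#' @return list of class `"MetricsReport"`: `confusion`, `P`, `R`, `F1`,
#'   `auroc`, `auprc`, `fbetaCurve`, `curves`, `thresholdTable`.
#' @export
metricsReport <- function(scores, truth, threshold = 0.5,
                          betaGrid = seq(0.1, 3.0, by = 0.1)) {
  cm <- confusionMatrix(scores, truth, threshold)
  pr <- suppressWarnings(prf(cm))
  curves <- rocPr(scores, truth)
  structure(list(confusion = cm, P = unname(pr["P"]), R = unname(pr["R"]),
                 F1 = unname(pr["F1"]), auroc = curves$auroc,
                 auprc = curves$auprc, fbetaCurve = fbetaCurve(cm, betaGrid),
                 curves = curves[c("roc", "pr")],
                 thresholdTable = curves$thresholdTable),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  # display rounding: 2 decimals, round-half-even; internals keep full precision
  r2 <- function(v) formatC(round(v, 2), format = "f", digits = 2)
  cat("MetricsReport @ threshold ", x$confusion$threshold, "\n", sep = "")
  cat("  precision ", r2(x$P), "  recall ", r2(x$R), "  F1 ", r2(x$F1), "\n",
      sep = "")
  cat("  AUROC ", r2(x$auroc), "  AUPRC ", r2(x$auprc), "\n", sep = "")
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes a TSV of scalar metrics and confusion counts, plus a JSON file of
#' the ROC / PR curve points and F-beta sweep.
#'
#' @param report a `"MetricsReport"`.
#' @param prefix output path prefix; writes `<prefix>_metrics.tsv` and
#'   `<prefix>_curves.json`.
#' @return the two paths, invisibly.
#' @export
writeMetricsReport <- function(report, prefix) {
  tsv <- paste0(prefix, "_metrics.tsv")
  js <- paste0(prefix, "_curves.json")
  cm <- report$confusion
  df <- data.frame(metric = c("TP", "FP", "FN", "TN", "threshold",
                              "precision", "recall", "F1", "AUROC", "AUPRC"),
                   value = c(cm$TP, cm$FP, cm$FN, cm$TN, cm$threshold,
                             report$P, report$R, report$F1, report$auroc,
                             report$auprc))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(roc = report$curves$roc, pr = report$curves$pr,
                            fbeta = report$fbetaCurve),
                       js, digits = NA, dataframe = "columns")
  invisible(c(tsv, js))
}
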