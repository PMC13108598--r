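#' Confusion counts between a predicted and a reference mask
#'
#' The positive class is "preserve".
#'
#' @param predicted Logical mask produced by a model.
#' @param truth Reference logical mask.
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @examples
#' confusionCounts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusionCounts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop(sprintf("mask lengths differ: %d vs %d",
                 length(predicted), length(truth)), call. = FALSE)
  }
  c(tp = sum(predicted & truth), tn = sum(!predicted & !truth),
    fp = sum(predicted & !truth), fn = sum(!predicted & truth))
}

#' Matthews correlation coefficient
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, the
#' correlation between predicted and reference assignments, in `[-1, 1]`.
#' When any marginal total is zero the ratio is 0/0; the conventional value
#' 0 is returned, which keeps degenerate alignments (e.g. masks that
#' preserve every column) from crashing an evaluation.
#'
#' @param counts Named vector from [confusionCounts()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  cc <- as.numeric(counts[c("tp", "tn", "fp", "fn")])
  tp <- cc[1L]; tn <- cc[2L]; fp <- cc[3L]; fn <- cc[4L]
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Accuracy
#'
#' Proportion of columns on which the model and the reference mask agree.
#'
#' @inheritParams mcc
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  cc <- as.numeric(counts[c("tp", "tn", "fp", "fn")])
  total <- sum(cc)
  if (total == 0) {
    stop("accuracy is undefined on zero columns", call. = FALSE)
  }
  (cc[1L] + cc[2L]) / total
}

#' F-beta score
#'
#' `(1 + beta^2) tp / ((1 + beta^2) tp + beta^2 fn + fp)`; recall is
#' weighted by `beta^2` relative to precision.  When `tp = 0` with any
#' positive error, the score is 0.
#'
#' @inheritParams mcc
#' @param beta Positive weight on recall.
#' @return Fraction in `[0, 1]`.
#' @export
fBeta <- function(counts, beta = 1) {
  assertScalarNumber(beta, "beta", lo = .Machine$double.xmin)
  cc <- as.numeric(counts[c("tp", "tn", "fp", "fn")])
  tp <- cc[1L]; fp <- cc[3L]; fn <- cc[4L]
  denom <- (1 + beta^2) * tp + beta^2 * fn + fp
  if (denom == 0) {
    return(if (tp + fp + fn == 0) 1 else 0)
  }
  (1 + beta^2) * tp / denom
}

#' Mean log loss
#'
#' `-(1/n) sum [y ln p + (1 - y) ln(1 - p)]` in nats; the objective the
#' model coefficients are trained against.
#'
#' @param p Preservation scores in `(0, 1)`.
#' @param truth Logical reference mask of the same length.
#' @return Non-negative mean log loss.
#' @export
logLoss <- function(p, truth) {
  if (length(p) != length(truth)) {
    stop(sprintf("lengths differ: %d scores vs %d labels",
                 length(p), length(truth)), call. = FALSE)
  }
  if (any(p <= 0) || any(p >= 1)) {
    stop("scores must lie strictly inside (0, 1)", call. = FALSE)
  }
  y <- as.numeric(truth)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped), collecting (false-positive rate, true-positive rate) points
#' from `(0, 0)` to `(1, 1)`.  The AUC is computed from ranks as the
#' Mann-Whitney statistic `P(score_pos > score_neg) + P(tie)/2`, which
#' equals the trapezoidal area under the tie-grouped curve.
#'
#' @param p Preservation scores.
#' @param truth Logical reference mask; both classes must be present.
#' @return List with `roc` (data frame of `fpr`, `tpr` in sweep order) and
#'   `auc`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))$auc
#' @export
rocAuc <- function(p, truth) {
  if (length(p) != length(truth)) {
    stop(sprintf("lengths differ: %d scores vs %d labels",
                 length(p), length(truth)), call. = FALSE)
  }
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L) {
    stop("ROC requires both classes in the reference mask", call. = FALSE)
  }
  # threshold sweep, highest first; predicted positive means score > thr
  thr <- sort(unique(p), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr) + 1L)
  for (i in seq_along(thr)) {
    pos <- p > thr[i]
    tpr[i] <- sum(pos & truth) / npos
    fpr[i] <- sum(pos & !truth) / nneg
  }
  tpr[length(thr) + 1L] <- 1
  fpr[length(thr) + 1L] <- 1
  r <- rank(p)  # average ranks handle ties as half-counts
  auc <- (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Dispatch a validation metric on confusion counts.
metricFromCounts <- function(counts, metric = c("mcc", "accuracy", "fbeta"),
                             beta = 1) {
  metric <- match.arg(metric)
  switch(metric,
         mcc = mcc(counts),
         accuracy = accuracy(counts),
         fbeta = fBeta(counts, beta = beta))
}

#' Build an evaluation report
#'
#' Bundles every test-stage metric for one set of columns: confusion counts
#' of the predicted vs. reference mask, MCC, accuracy, F-beta, mean log
#' loss, the confidence score C of the preservation scores, and (when both
#' classes occur in the reference) the ROC curve and AUC.
#'
#' @param p Preservation scores, one per column.
#' @param predicted Logical mask the model produced (may include bootstrap
#'   decisions, so it is passed separately from `p`).
#' @param truth Reference logical mask.
#' @param beta Beta for the F-beta score.
#' @return An [EvaluationReport-class].
#' @export
evaluationReport <- function(p, predicted, truth, beta = 1) {
  cc <- confusionCounts(predicted, truth)
  roc <- data.frame(fpr = numeric(0), tpr = numeric(0))
  auc <- NA_real_
  if (sum(truth) > 0L && sum(!truth) > 0L) {
    ra <- rocAuc(p, truth)
    roc <- ra$roc
    auc <- ra$auc
  }
  new("EvaluationReport", confusion = as.integer(cc) |>
        setNames(c("tp", "tn", "fp", "fn")),
      mcc = mcc(cc), accuracy = accuracy(cc),
      fBeta = fBeta(cc, beta = beta), beta = beta,
      logLoss = logLoss(p, truth), confidence = confidenceScore(p),
      roc = roc, auc = auc)
}

#' Convert an evaluation report to a plain list
#'
#' @param report An [EvaluationReport-class].
#' @param includeRoc Include the ROC points (can be long).
#' @return A list suitable for JSON serialization.
#' @export
reportAsList <- function(report, includeRoc = TRUE) {
  stopifnot(is(report, "EvaluationReport"))
  out <- list(
    confusion = as.list(report@confusion),
    mcc = report@mcc, accuracy = report@accuracy,
    f_beta = report@fBeta, beta = report@beta,
    log_loss = report@logLoss, confidence = report@confidence,
    auc = report@auc)
  if (includeRoc) {
    out$roc <- report@roc
  }
  out
}

#' Write an evaluation report
#'
#' @param report An [EvaluationReport-class].
#' @param path Output path.
#' @param format `"json"` for machine-readable output, `"text"` for the
#'   human-readable summary printed by `show()`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(as.character(jsonlite::toJSON(reportAsList(report),
                                             auto_unbox = TRUE, digits = I(17),
                                             pretty = TRUE, na = "null")),
               path)
  } else {
    txt <- utils::capture.output(show(report))
    writeLines(txt, path)
  }
  invisible(path)
}
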