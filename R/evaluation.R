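#' @include AllClasses.R
NULL

#' Confusion counts at a threshold
#'
#' The prediction is positive (cancer) iff the score strictly exceeds the
#' threshold; a score exactly at the threshold is predicted non-cancer.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 ground-truth labels (1 = cancer).
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("empty input")
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.integer(scores > threshold)
  c(TP = sum(pred == 1L & labels == 1),
    TN = sum(pred == 0L & labels == 0),
    FP = sum(pred == 1L & labels == 0),
    FN = sum(pred == 0L & labels == 1))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), F1 = 2TP/(2TP+FP+FN). A metric whose denominator is
#' zero is reported as 0 and flagged in the `degenerate` attribute (with a
#' warning), so that fold aggregation stays total.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   with attribute `degenerate` naming any zero-denominator metrics.
#' @export
metricsFromCounts <- function(counts) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  degenerate <- character()
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  out <- c(
    accuracy = safe(TP + TN, TP + TN + FP + FN, "accuracy"),
    precision = safe(TP, TP + FP, "precision"),
    recall = safe(TP, TP + FN, "recall"),
    f1 = safe(2 * TP, 2 * TP + FP + FN, "f1")
  )
  if (length(degenerate)) {
    warning("zero denominator, metric reported as 0: ",
            paste(degenerate, collapse = ", "))
    attr(out, "degenerate") <- degenerate
  }
  out
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, with ties given half credit.
#' Implemented with average ranks; equivalent to exhaustive pair counting.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold optimisation by the Youden index
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus -Inf/+Inf sentinels. Returns the candidate maximising
#' J = sensitivity + specificity - 1 (prediction rule: score strictly above
#' the threshold is positive); ties resolve to the smallest threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `threshold` and `J`.
#' @export
youdenThreshold <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  J <- vapply(cand, function(t) {
    sens <- sum(scores > t & labels == 1) / n1
    spec <- sum(scores <= t & labels == 0) / n0
    sens + spec - 1
  }, 0)
  # ties (within numerical tolerance, since equal J can be assembled from
  # different sens/spec pairs) resolve to the smallest threshold
  best <- which(J >= max(J) - 1e-9)[1L]
  list(threshold = cand[best], J = J[best])
}

#' Aggregate per-fold metrics as mean and standard deviation
#'
#' Arithmetic mean and sample (n-1) standard deviation of each metric across
#' folds, as used for cross-validated "mean +/- sd" reporting.
#'
#' @param perFold list (>= 2) of named numeric metric vectors, or a numeric
#'   matrix with one row per fold.
#' @return list with `mean`, `sd` (named numeric vectors) and `perFold`
#'   (matrix, folds x metrics).
#' @export
aggregateCV <- function(perFold) {
  m <- if (is.matrix(perFold)) perFold else do.call(rbind, perFold)
  if (nrow(m) < 2L) stop("need at least 2 folds to aggregate")
  list(mean = colMeans(m),
       sd = apply(m, 2L, stats::sd),
       perFold = m)
}

#' Format an aggregated cross-validation report
#'
#' AUC to 3 decimals; percentage metrics to 1 decimal, scaled to percent.
#'
#' @param agg output of [aggregateCV()].
#' @return data.frame with columns `metric`, `mean`, `sd`, `display`.
#' @export
formatCVReport <- function(agg) {
  metric <- names(agg$mean)
  display <- vapply(seq_along(metric), function(i) {
    if (grepl("auc", metric[i], ignore.case = TRUE)) {
      sprintf("%.3f ± %.3f", agg$mean[i], agg$sd[i])
    } else {
      sprintf("%.1f ± %.1f", 100 * agg$mean[i], 100 * agg$sd[i])
    }
  }, "")
  data.frame(metric = metric, mean = unname(agg$mean), sd = unname(agg$sd),
             display = display, stringsAsFactors = FALSE)
}

#' Full evaluation of scores against labels
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold; `"youden"` optimises it by
#'   [youdenThreshold()].
#' @return named numeric vector: accuracy, precision, recall, f1, auc,
#'   threshold.
#' @export
evaluateScores <- function(scores, labels, threshold = 0.5) {
  thr <- if (identical(threshold, "youden"))
    youdenThreshold(scores, labels)$threshold else threshold
  cc <- confusionCounts(scores, labels, thr)
  met <- suppressWarnings(metricsFromCounts(cc))
  c(met, auc = rocAuc(scores, labels), threshold = thr)
}
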