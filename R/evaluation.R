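#' Classification metrics from confusion counts
#'
#' Standard forms: accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, and F1
#' the harmonic mean of precision and sensitivity. A metric whose
#' denominator is zero is reported as `NA` and listed in the `"undefined"`
#' attribute — never silently 0.
#'
#' @param TP,TN,FP,FN non-negative integer confusion counts; at least one
#'   must be positive.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, with attribute `undefined` naming any undefined
#'   entries.
#' @examples
#' classificationMetrics(TP = 9, TN = 8, FP = 1, FN = 2)
#' @export
classificationMetrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all confusion counts are zero")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- safe(TP + TN, TP + TN + FP + FN)
  sen <- safe(TP, TP + FN)
  spe <- safe(TN, TN + FP)
  pre <- safe(TP, TP + FP)
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_
        else 2 * pre * sen / (pre + sen)
  out <- c(accuracy = acc, sensitivity = sen, specificity = spe,
           precision = pre, f1 = f1)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

.maskPixels <- function(x) {
  if (is(x, "BinaryMask")) pixels(x) else {
    stopifnot(all(x %in% c(0, 1)))
    as.matrix(x)
  }
}

#' Dice coefficient between two binary masks
#'
#' `2|P intersect G| / (|P| + |G|)`. Two empty masks agree perfectly on the
#' absence of a lesion and score 1, flagged via the `bothEmpty` attribute.
#'
#' @param P,G predicted and ground-truth masks ([BinaryMask] or 0/1 matrix)
#'   of identical shape.
#' @return a number in `[0, 1]`.
#' @export
diceCoefficient <- function(P, G) {
  p <- .maskPixels(P); g <- .maskPixels(G)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(structure(1, bothEmpty = TRUE))
  2 * sum(p * g) / (sp + sg)
}

#' Intersection over union (Jaccard index) between two binary masks
#'
#' `|P intersect G| / |P union G|`; both-empty masks score 1 (flagged). For
#' every mask pair `dice = 2 iou / (1 + iou)`.
#'
#' @inheritParams diceCoefficient
#' @return a number in `[0, 1]`.
#' @export
iouScore <- function(P, G) {
  p <- .maskPixels(P); g <- .maskPixels(G)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  inter <- sum(p * g)
  uni <- sum(p) + sum(g) - inter
  if (uni == 0) return(structure(1, bothEmpty = TRUE))
  inter / uni
}

#' Aggregate per-image scores to the case level
#'
#' Unweighted mean over each case's views, so a case imaged in both CC and
#' MLO counts once — the per-case unit that the bootstrap and the paired
#' tests resample.
#'
#' @param scores data.frame with columns `case_id` and `score` (a `view`
#'   column may be present; it is ignored by the mean).
#' @return data.frame with one row per case: `case_id`, `score`.
#' @export
aggregateCaseLevel <- function(scores) {
  stopifnot(all(c("case_id", "score") %in% names(scores)),
            all(is.finite(scores$score)))
  m <- tapply(scores$score, scores$case_id, mean)
  data.frame(case_id = names(m), score = as.numeric(m),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentile bootstrap confidence interval for a mean score
#'
#' Cases are resampled with replacement; the statistic is the mean per
#' resample; the interval is the percentile interval at
#' `(1 - level)/2` and `1 - (1 - level)/2` with linear-interpolation
#' quantiles. Mean, SD (sample) and median are computed on the original
#' scores.
#'
#' @param scores per-case scores (at least 2).
#' @param nResamples bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return a list of class `MetricSummary`: `mean`, `sd`, `median`,
#'   `ciLow`, `ciHigh`, `nCases`, `nResamples`, `level`.
#' @examples
#' bootstrapCI(c(0.8, 0.9, 0.85, 0.7, 0.95), seed = 1)
#' @export
bootstrapCI <- function(scores, nResamples = 1000, level = 0.95, seed = 1) {
  n <- length(scores)
  if (n < 2) stop("bootstrap needs at least 2 scores")
  stopifnot(all(is.finite(scores)), nResamples >= 1, level > 0, level < 1)
  means <- .withSeed(seed, {
    idx <- matrix(sample.int(n, n * nResamples, replace = TRUE),
                  nrow = nResamples)
    rowMeans(matrix(scores[idx], nrow = nResamples))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(mean = mean(scores), sd = stats::sd(scores),
                 median = stats::median(scores),
                 ciLow = ci[1], ciHigh = ci[2],
                 nCases = n, nResamples = nResamples, level = level),
            class = "MetricSummary")
}

#' @export
print.MetricSummary <- function(x, ...) {
  cat(sprintf(
    "MetricSummary: mean %.4f, sd %.4f, median %.4f, %g%% CI [%.4f, %.4f] (n = %d, B = %d)\n",
    x$mean, x$sd, x$median, 100 * x$level, x$ciLow, x$ciHigh,
    x$nCases, x$nResamples))
  invisible(x)
}

#' Paired t-test between two matched score series
#'
#' Classic paired t on the differences `d = a - b` (sample SD, `df = n - 1`,
#' two-sided p). Identical series return `t = 0, p = 1` (nothing to test);
#' constant nonzero differences have no variance for the statistic and are
#' an error.
#'
#' @param a,b equal-length numeric vectors of per-case scores (n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
pairedTTest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  if (stats::sd(d) == 0) {
    if (d[1] == 0) return(list(t = 0, df = length(d) - 1, p = 1))
    stop("paired t-test is undefined: differences are constant and nonzero ",
         "(zero variance)")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Confusion counts from probabilistic predictions
#'
#' @param prob predicted probabilities of the positive class.
#' @param truth 0/1 (or logical) ground-truth labels.
#' @param threshold decision threshold (default 0.5).
#' @return named counts `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(prob, truth, threshold = 0.5) {
  stopifnot(length(prob) == length(truth))
  pred <- prob >= threshold
  truth <- as.logical(truth)
  c(TP = sum(pred & truth), TN = sum(!pred & !truth),
    FP = sum(pred & !truth), FN = sum(!pred & truth))
}

#' Metric sweep over decision thresholds
#'
#' Utility for ROC/precision-recall style curves; no single operating point
#' is privileged.
#'
#' @inheritParams confusionCounts
#' @param thresholds thresholds to sweep.
#' @return data.frame with `threshold`, `tpr`, `fpr`, `precision`.
#' @export
thresholdSweep <- function(prob, truth,
                           thresholds = seq(0, 1, by = 0.05)) {
  rows <- lapply(thresholds, function(th) {
    cc <- confusionCounts(prob, truth, th)
    data.frame(
      threshold = th,
      tpr = if (cc["TP"] + cc["FN"] == 0) NA_real_
            else unname(cc["TP"] / (cc["TP"] + cc["FN"])),
      fpr = if (cc["FP"] + cc["TN"] == 0) NA_real_
            else unname(cc["FP"] / (cc["FP"] + cc["TN"])),
      precision = if (cc["TP"] + cc["FP"] == 0) NA_real_
                  else unname(cc["TP"] / (cc["TP"] + cc["FP"])))
  })
  do.call(rbind, rows)
}
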