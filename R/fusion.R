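# Vertebra-wise evaluation: OR/AND fusion of binary detectors, confusion
# matrices, the four screening metrics with Wilson 95% CIs, and ROC/AUC.

checkAligned <- function(a, b) {
  if (!identical(as.integer(a$level), as.integer(b$level)))
    stop("call sets are not aligned: vertebra index sets differ")
}

#' Fuse two detectors' calls
#'
#' \code{complement_negative} re-examines primary-negative vertebrae with the
#' secondary detector: fused positive iff primary OR secondary positive
#' (primary positives are kept). \code{confirm_positive} requires the
#' secondary detector to confirm primary positives: fused positive iff
#' primary AND secondary positive (primary negatives stay negative).
#' \code{standalone} returns the primary calls unchanged.
#'
#' @param primary,secondary call data.frames with columns \code{level},
#'   \code{positive} (and optionally \code{score}), over the same vertebra
#'   index set.
#' @param mode one of \code{"standalone"}, \code{"complement_negative"},
#'   \code{"confirm_positive"}.
#' @return a call data.frame; the fused score is the pairwise max
#'   (complement) or min (confirm) of the component scores when both carry
#'   scores.
#' @export
fuseCalls <- function(primary, secondary,
                      mode = c("standalone", "complement_negative",
                               "confirm_positive")) {
  mode <- match.arg(mode)
  if (mode == "standalone") return(primary)
  checkAligned(primary, secondary)
  positive <- switch(mode,
    complement_negative = primary$positive | secondary$positive,
    confirm_positive = primary$positive & secondary$positive)
  out <- data.frame(level = primary$level, positive = positive)
  if (!is.null(primary$score) && !is.null(secondary$score))
    out$score <- if (mode == "complement_negative")
      pmax(primary$score, secondary$score)
    else pmin(primary$score, secondary$score)
  out
}

#' Vertebra-wise confusion matrix
#'
#' @param truth logical vector of per-vertebra acute truth flags, or a
#'   data.frame with columns \code{level} and \code{acute}.
#' @param calls call data.frame with columns \code{level}, \code{positive}.
#' @return a \linkS4class{ConfusionMatrix}.
#' @examples
#' cm <- confusionMatrix(c(TRUE, FALSE, TRUE),
#'   data.frame(level = 1:3, positive = c(TRUE, TRUE, FALSE)))
#' counts(cm)
#' @export
confusionMatrix <- function(truth, calls) {
  if (is.data.frame(truth)) {
    if (!identical(as.integer(truth$level), as.integer(calls$level)))
      stop("truth and calls are not aligned: vertebra index sets differ")
    truth <- truth$acute
  } else if (length(truth) != nrow(calls)) {
    stop("truth and calls are not aligned: lengths differ")
  }
  stopifnot(is.logical(truth), !anyNA(truth), !anyNA(calls$positive))
  pos <- calls$positive
  new("ConfusionMatrix",
      tp = sum(truth & pos), fp = sum(!truth & pos),
      tn = sum(!truth & !pos), fn = sum(truth & !pos))
}

# Direct constructor from the four counts.
#' @rdname confusionMatrix
#' @param tp,fp,tn,fn counts (alternative direct construction).
#' @export
confusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n counts, 0 <= successes <= n, n > 0.
#' @param alpha two-sided level (default 0.05 for a 95\% interval).
#' @return numeric \code{c(low, high)} in percent, within [0, 100].
#' @examples
#' wilsonCI(102, 148)  # 61.06 75.82 (at 2 decimals)
#' @export
wilsonCI <- function(successes, n, alpha = 0.05) {
  if (n <= 0) stop("n must be > 0")
  stopifnot(successes >= 0, successes <= n)
  z <- stats::qnorm(1 - alpha / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  pmin(pmax(c(low = center - half, high = center + half) * 100, 0), 100)
}

#' Screening metrics with Wilson 95\% CIs
#'
#' sensitivity = tp/(tp+fn); specificity = tn/(tn+fp); accuracy =
#' (tp+tn)/total; precision = tp/(tp+fp). Values in percent at full
#' precision; round at I/O. The CI is the Wilson score interval on the same
#' numerator/denominator.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @param which metric name.
#' @param alpha CI level (default 0.05).
#' @return list with \code{value}, \code{ciLow}, \code{ciHigh}, \code{n}
#'   (denominator), \code{method = "wilson"}.
#' @examples
#' detectionMetric(confusionCounts(102, 82, 800, 46), "sensitivity")$value
#' @export
detectionMetric <- function(cm, which = c("sensitivity", "specificity",
                                          "accuracy", "precision"),
                            alpha = 0.05) {
  which <- match.arg(which)
  k <- counts(cm)
  num <- switch(which, sensitivity = k["tp"], specificity = k["tn"],
                accuracy = k["tp"] + k["tn"], precision = k["tp"])
  den <- switch(which, sensitivity = k["tp"] + k["fn"],
                specificity = k["tn"] + k["fp"], accuracy = sum(k),
                precision = k["tp"] + k["fp"])
  if (den == 0) stop(sprintf("metric '%s' undefined: zero denominator", which))
  ci <- wilsonCI(num, den, alpha)
  list(value = unname(num / den * 100), ciLow = unname(ci[1]),
       ciHigh = unname(ci[2]), n = unname(den), method = "wilson")
}

#' All four metrics as a table
#'
#' @inheritParams detectionMetric
#' @param digits if non-NULL, round (half-up) values and CI bounds for
#'   display/export.
#' @return data.frame with one row per metric; a metric whose denominator is
#'   zero (e.g. precision of a detector that never calls positive) is
#'   reported as \code{NA} rather than an error.
#' @export
metricTable <- function(cm, alpha = 0.05, digits = NULL) {
  ms <- c("sensitivity", "specificity", "accuracy", "precision")
  rows <- lapply(ms, function(m) {
    x <- tryCatch(detectionMetric(cm, m, alpha),
                  error = function(e) list(value = NA_real_,
                                           ciLow = NA_real_,
                                           ciHigh = NA_real_, n = 0L))
    data.frame(metric = m, value = x$value, ci_low = x$ciLow,
               ci_high = x$ciHigh, n = x$n)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits))
    out[c("value", "ci_low", "ci_high")] <-
      lapply(out[c("value", "ci_low", "ci_high")], roundHalfUp, digits)
  out
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps over all distinct score values as thresholds (calls positive iff
#' score >= threshold); ties are grouped at one threshold. Endpoints (0,0)
#' and (1,1) are included and the AUC is the trapezoidal area.
#'
#' @param truth logical vector (>= 1 positive and >= 1 negative required).
#' @param scores numeric per-vertebra scores.
#' @return a \linkS4class{ROCCurve}.
#' @examples
#' auc(rocCurve(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.2, 0.1)))  # 1
#' @export
rocCurve <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), !anyNA(truth), !anyNA(scores))
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0 || nNeg == 0)
    stop("ROC undefined: truth contains a single class")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(truth & scores >= t) / nPos, 1)
  fpr <- vapply(thr, function(t) sum(!truth & scores >= t) / nNeg, 1)
  pts <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  aucVal <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                   utils::tail(pts$tpr, -1)) / 2)
  new("ROCCurve", points = pts, auc = aucVal)
}

#' Single-operating-point ROC for a binary detector
#'
#' A threshold-free binary detector has one (fpr, tpr) point; the curve joins
#' it to (0,0) and (1,1).
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return a \linkS4class{ROCCurve} with three points.
#' @export
rocFromConfusion <- function(cm) {
  k <- counts(cm)
  tpr <- k["tp"] / (k["tp"] + k["fn"])
  fpr <- k["fp"] / (k["fp"] + k["tn"])
  pts <- data.frame(threshold = c(Inf, NA, -Inf),
                    fpr = unname(c(0, fpr, 1)), tpr = unname(c(0, tpr, 1)))
  aucVal <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                   utils::tail(pts$tpr, -1)) / 2)
  new("ROCCurve", points = pts, auc = aucVal)
}
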