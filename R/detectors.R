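# Deterministic contour-irregularity scoring: a desk-scale stand-in for
# learned detectors, built on the premise that acute fractures are visible as
# irregularities of the cortical contour (step-offs, break fissures), while a
# clean cortex -- however compressed -- fits a quadrilateral closely.

# Default score normalization: a 3-px step yields score > 0.6.
IRREG_R0 <- 2   # residual scale, pixels
IRREG_D0 <- 1   # discontinuity scale, count

contourCoords <- function(contour) {
  idx <- which(contour != 0, arr.ind = TRUE)
  cbind(x = idx[, "col"] - 0.5, y = idx[, "row"] - 0.5)
}

#' Fit a reference quadrilateral to a vertebral contour
#'
#' Corners are initialized at the contour's extreme points along the four
#' diagonal combinations of its principal axes, then refined by Nelder--Mead
#' to minimize the mean point-to-edge distance. Deterministic.
#'
#' @param contour binary contour mask (or a 2-column x/y coordinate matrix).
#' @return 4 x 2 matrix of corner coordinates (columns x, y), in cyclic order.
#' @export
fitReferenceQuad <- function(contour) {
  pts <- if (is.matrix(contour) && ncol(contour) == 2 &&
             !all(contour %in% c(0, 1))) contour else contourCoords(contour)
  if (nrow(pts) < 8) stop("need at least 8 contour pixels")
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  ev <- eigen(stats::cov(cpts), symmetric = TRUE)
  if (ev$values[2] < 1e-6 * ev$values[1])
    stop("degenerate contour: pixels are collinear")
  u <- ev$vectors[, 1]; v <- ev$vectors[, 2]
  corners <- rbind(
    pts[which.max(cpts %*% (u + v)), ],
    pts[which.max(cpts %*% (u - v)), ],
    pts[which.max(cpts %*% (-u - v)), ],
    pts[which.max(cpts %*% (-u + v)), ])
  # cyclic order around the centroid
  ang <- atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1])
  corners <- corners[order(ang), , drop = FALSE]

  obj <- function(par) mean(pointPolygonDist(pts, matrix(par, 4, 2)))
  fit <- stats::optim(as.vector(corners), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  matrix(fit$par, 4, 2, dimnames = list(NULL, c("x", "y")))
}

# Order contour pixels as a traversal chain: start at the topmost-leftmost
# pixel, then repeatedly step to the nearest unvisited pixel (ties broken
# clockwise, i.e. by angle around the shape centroid).
contourChain <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  visited <- logical(n)
  ord <- integer(n)
  cur <- order(pts[, 2], pts[, 1])[1]  # topmost, then leftmost
  for (i in seq_len(n)) {
    ord[i] <- cur
    visited[cur] <- TRUE
    if (i == n) break
    rest <- which(!visited)
    d2 <- (pts[rest, 1] - pts[cur, 1])^2 + (pts[rest, 2] - pts[cur, 2])^2
    best <- rest[d2 == min(d2)]
    if (length(best) > 1L) {
      # clockwise preference in image coordinates (y down)
      angCur <- atan2(pts[cur, 2] - ctr[2], pts[cur, 1] - ctr[1])
      angBest <- atan2(pts[best, 2] - ctr[2], pts[best, 1] - ctr[1])
      rel <- (angBest - angCur) %% (2 * pi)
      best <- best[which.min(rel)]
    }
    cur <- best[1]
  }
  ord
}

#' Score contour irregularity against a fitted quadrilateral
#'
#' \code{residual} is the maximum point-to-edge distance from the contour to
#' the quadrilateral. \code{discontinuities} counts cortical-continuity
#' violations along the contour traversal (clockwise from the
#' topmost-leftmost pixel): steps between traversal-adjacent pixels longer
#' than \code{jumpThreshold}, plus inward excursions -- maximal traversal runs
#' lying deeper than \code{jumpThreshold} inside the quadrilateral, the
#' signature of a break fissure. The score combines both:
#' \code{1 - exp(-(residual / r0 + discontinuities / d0))}, in [0, 1], and is
#' exactly 0 for a contour lying on the quadrilateral.
#'
#' @param contour binary contour mask (or x/y coordinate matrix).
#' @param quad 4 x 2 corner matrix from \code{\link{fitReferenceQuad}};
#'   fitted automatically if missing.
#' @param jumpThreshold jump/excursion threshold in pixels (default 2).
#' @param r0,d0 score normalization constants.
#' @return list with \code{residual}, \code{discontinuities}, \code{score}.
#' @export
irregularityScore <- function(contour, quad = NULL, jumpThreshold = 2,
                              r0 = IRREG_R0, d0 = IRREG_D0) {
  pts <- if (is.matrix(contour) && ncol(contour) == 2 &&
             !all(contour %in% c(0, 1))) contour else contourCoords(contour)
  if (is.null(quad)) quad <- fitReferenceQuad(pts)
  d <- pointPolygonDist(pts, quad)
  residual <- max(d)

  ord <- contourChain(pts)
  p <- pts[ord, , drop = FALSE]
  stepLen <- sqrt(rowSums(diff(p)^2))
  jumps <- sum(stepLen > jumpThreshold)
  # inward excursions: runs of traversal pixels deeper than the threshold
  deep <- d[ord] > jumpThreshold
  excursions <- sum(diff(c(FALSE, deep)) == 1)
  discontinuities <- jumps + excursions

  score <- 1 - exp(-(residual / r0 + discontinuities / d0))
  list(residual = residual, discontinuities = discontinuities, score = score)
}

#' Score every vertebra of a label mask for contour irregularity
#'
#' Convenience wrapper: extracts each label's contour, fits the reference
#' quadrilateral and scores it.
#'
#' @param mask integer label mask.
#' @param jumpThreshold,r0,d0 passed to \code{\link{irregularityScore}}.
#' @return data.frame with columns \code{level}, \code{residual},
#'   \code{discontinuities}, \code{score}.
#' @export
scoreSpine <- function(mask, jumpThreshold = 2, r0 = IRREG_R0, d0 = IRREG_D0) {
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  rows <- lapply(labels, function(lab) {
    sc <- irregularityScore(extractContour(mask, lab),
                            jumpThreshold = jumpThreshold, r0 = r0, d0 = d0)
    data.frame(level = lab, residual = sc$residual,
               discontinuities = sc$discontinuities, score = sc$score)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold scores into detection calls
#'
#' @param scores numeric vector of per-vertebra confidence scores in [0, 1].
#' @param threshold calling threshold; positive iff score >= threshold.
#' @param levels vertebra indices (default sequential).
#' @return data.frame with columns \code{level}, \code{positive},
#'   \code{score}; the threshold is recorded as attribute
#'   \code{"threshold"} for ROC sweeps.
#' @examples
#' callFromScores(c(0.2, 0.7), 0.5)$positive  # FALSE TRUE
#' @export
callFromScores <- function(scores, threshold, levels = seq_along(scores)) {
  stopifnot(all(scores >= 0 & scores <= 1))
  out <- data.frame(level = levels, positive = scores >= threshold,
                    score = scores)
  attr(out, "threshold") <- threshold
  out
}
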