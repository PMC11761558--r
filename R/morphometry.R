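# Automated vertebral morphometry on label masks: anterior/middle/posterior
# height reading, height loss ratio (HLR), and Genant semiquantitative
# grading.

#' Construct a MeasurementConfig
#'
#' @param samplingFractions fractions of the AP chord at which the anterior,
#'   middle and posterior heights are read (strictly increasing, in (0,1)).
#' @param axisMethod \code{"principal_axis"} (default; each body is rotated to
#'   its principal axis before vertical extents are read — required for curved
#'   spines) or \code{"bounding_box"}.
#' @param hlrVariant \code{"printed"} (default): HLR = (1 - min(ha, hm)/hp) *
#'   100, which can be negative when the posterior height is the lowest;
#'   \code{"min_over_max"}: (1 - min/max over all three) * 100, which is
#'   always non-negative.
#' @param bandWidth width of the averaging band around each sampling fraction,
#'   as a fraction of the AP extent.
#' @return a \linkS4class{MeasurementConfig}.
#' @export
measurementConfig <- function(samplingFractions = c(0.10, 0.50, 0.90),
                              axisMethod = c("principal_axis", "bounding_box"),
                              hlrVariant = c("printed", "min_over_max"),
                              bandWidth = 0.05) {
  new("MeasurementConfig", samplingFractions = samplingFractions,
      axisMethod = match.arg(axisMethod), hlrVariant = match.arg(hlrVariant),
      bandWidth = bandWidth)
}

# Orientation of a body's long (anterior-posterior) axis, estimated as the
# direction of the minimal-area bounding rectangle (rotating calipers on the
# convex hull). Unlike a raw pixel PCA this locks onto the intact inferior
# cortex, so a deformity of the superior endplate does not tilt the measuring
# frame; for symmetric bodies it coincides with the principal axis.
bodyAxisAngle <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  m <- nrow(hull)
  best <- NULL
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    a <- atan2(e[2], e[1])
    rot <- cbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))  # rotate by -a
    r <- hull %*% rot
    ext <- c(diff(range(r[, 1])), diff(range(r[, 2])))
    if (is.null(best) || prod(ext) < best$area - 1e-9)
      best <- list(area = prod(ext), angle = a, ext = ext)
  }
  ang <- if (best$ext[1] >= best$ext[2]) best$angle else best$angle + pi / 2
  # normalize to (-pi/2, pi/2]
  ang <- ((ang + pi / 2) %% pi) - pi / 2
  ang
}

unmeasurableError <- function(msg) {
  structure(class = c("unmeasurableVertebra", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Measure anterior/middle/posterior heights of one vertebra
#'
#' The body's pixel set is rotated to its long (anterior--posterior) axis (or
#' used as-is with \code{axisMethod = "bounding_box"}); heights are the
#' vertical pixel extents of the column bands centered at the three sampling
#' fractions of the AP extent.
#'
#' @param mask integer label mask.
#' @param vertebraId label to measure (>= 1).
#' @param config a \linkS4class{MeasurementConfig}.
#' @param pixelSpacing physical size of one pixel; heights are multiplied by
#'   it (default 1 = report in pixels).
#' @return named numeric vector \code{c(ha, hm, hp)}.
#' @examples
#' mask <- matrix(0L, 30, 40); mask[5:25, 6:35] <- 1L
#' measureHeights(mask, 1)  # 21 21 21
#' @export
measureHeights <- function(mask, vertebraId, config = measurementConfig(),
                           pixelSpacing = 1) {
  validObject(config)
  idx <- which(mask == vertebraId, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop(sprintf("label %s absent from mask", format(vertebraId)))
  if (nrow(idx) < 20L)
    stop(unmeasurableError(sprintf(
      "label %s has %d pixels (< 20): unmeasurable", format(vertebraId),
      nrow(idx))))
  # pixel centers in the 0-based geometry convention (x right, y down)
  pts <- cbind(x = idx[, "col"] - 0.5, y = idx[, "row"] - 0.5)

  if (config@axisMethod == "principal_axis") {
    theta <- bodyAxisAngle(pts)
    rot <- cbind(c(cos(theta), sin(theta)), c(-sin(theta), cos(theta)))
    pts <- pts %*% rot   # rotate by -theta: long axis -> horizontal
    colnames(pts) <- c("x", "y")
  }

  ap <- max(pts[, 1]) - min(pts[, 1]) + 1
  si <- max(pts[, 2]) - min(pts[, 2]) + 1
  if (ap < 3 || si < 3)
    stop(unmeasurableError(sprintf(
      "label %s degenerate (extent %0.f x %0.f px): unmeasurable",
      format(vertebraId), ap, si)))

  x0 <- min(pts[, 1])
  hw <- config@bandWidth / 2 * ap
  h <- vapply(config@samplingFractions, function(f) {
    ctrX <- x0 + f * ap
    sel <- abs(pts[, 1] - ctrX) <= hw
    if (!any(sel)) sel <- abs(pts[, 1] - ctrX) <= 0.5  # fall back to nearest column
    max(pts[sel, 2]) - min(pts[sel, 2]) + 1
  }, 1)
  stats::setNames(h * pixelSpacing, c("ha", "hm", "hp"))
}

#' Height loss ratio
#'
#' The printed variant is HLR = (1 - min(ha, hm) / hp) * 100 [\%]; it may be
#' negative when the posterior height is lower than both the anterior and
#' middle heights (e.g. physiological wedging of the lowest lumbar levels).
#' The \code{min_over_max} variant, (1 - min / max) * 100 over all three
#' heights, treats any height asymmetry as loss.
#'
#' @param heights numeric vector \code{c(ha, hm, hp)} (a \code{HeightTriple}).
#' @param variant \code{"printed"} or \code{"min_over_max"}.
#' @return HLR in percent (full precision; round at I/O).
#' @examples
#' computeHLR(c(16, 18, 21))              # 23.8095...
#' computeHLR(c(12, 15, 10))              # -20
#' computeHLR(c(12, 15, 10), "min_over_max")  # 33.33...
#' @export
computeHLR <- function(heights, variant = c("printed", "min_over_max")) {
  variant <- match.arg(variant)
  stopifnot(length(heights) == 3L)
  ha <- heights[[1]]; hm <- heights[[2]]; hp <- heights[[3]]
  if (is.na(hp) || hp <= 0) stop("posterior height must be > 0")
  if (variant == "printed") (1 - min(ha, hm) / hp) * 100
  else (1 - min(ha, hm, hp) / max(ha, hm, hp)) * 100
}

#' Genant semiquantitative grade from HLR
#'
#' Half-open intervals: normal (HLR < 20\%), mild (20\% <= HLR < 25\%),
#' moderate (25\% <= HLR < 40\%), severe (HLR >= 40\%). Negative HLR is
#' normal. Mild compression does not count as a vertebral compression
#' fracture.
#'
#' @param hlr numeric vector of HLR percentages.
#' @return factor with levels normal, mild, moderate, severe.
#' @examples
#' gradeGenant(c(19.99, 20, 25, 40, -20))
#' @export
gradeGenant <- function(hlr) {
  stopifnot(all(is.finite(hlr)))
  cut(hlr, breaks = c(-Inf, 20, 25, 40, Inf), labels = GENANT_GRADES,
      right = FALSE)
}

#' Measure every vertebra in a label mask
#'
#' One record per label: heights, HLR, Genant grade, and the VCF flag
#' (grade moderate or severe; mild never counts). Unmeasurable bodies (fewer
#' than 20 pixels or extent below 3 px) are reported with \code{NA} heights,
#' grade \code{normal} and a warning.
#'
#' @inheritParams measureHeights
#' @return data.frame with columns \code{level}, \code{ha}, \code{hm},
#'   \code{hp}, \code{hlr}, \code{grade}, \code{vcf_flag}.
#' @export
measureSpine <- function(mask, config = measurementConfig(), pixelSpacing = 1) {
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (length(labels) == 0L) stop("mask contains no vertebra labels")
  rows <- lapply(labels, function(lab) {
    h <- tryCatch(measureHeights(mask, lab, config, pixelSpacing),
                  unmeasurableVertebra = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    c(ha = NA_real_, hm = NA_real_, hp = NA_real_)
                  })
    hlr <- if (anyNA(h)) NA_real_ else computeHLR(h, config@hlrVariant)
    grade <- if (is.na(hlr)) factor("normal", levels = GENANT_GRADES)
             else gradeGenant(hlr)
    data.frame(level = lab, ha = h[[1]], hm = h[[2]], hp = h[[3]],
               hlr = hlr, grade = as.character(grade),
               vcf_flag = as.character(grade) %in% c("moderate", "severe"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
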