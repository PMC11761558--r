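#' @import methods
NULL

DEFORMITY_KINDS <- c("wedge", "biconcave", "crush", "step_off", "cortical_break")
ACUTE_MARKER_KINDS <- c("step_off", "cortical_break")
GENANT_GRADES <- c("normal", "mild", "moderate", "severe")
FUSION_MODES <- c("standalone", "complement_negative", "confirm_positive")

#' DeformitySpec: a single vertebral deformity
#'
#' Describes one deformity applied to one vertebral body of a spine phantom.
#' \code{wedge}, \code{biconcave} and \code{crush} remove \code{heightLoss}
#' pixels from the anterior, middle, or all three generative heights,
#' respectively. \code{step_off} displaces a stretch of the superior endplate
#' downward by \code{offset} pixels (an abrupt cortical step), and
#' \code{cortical_break} carves a narrow fissure of depth \code{gapLen} pixels
#' into the superior cortex. The two latter kinds are acute fracture markers
#' and force \code{acute = TRUE}.
#'
#' @slot level integer vertebra index (1 = topmost body).
#' @slot kind one of \code{"wedge"}, \code{"biconcave"}, \code{"crush"},
#'   \code{"step_off"}, \code{"cortical_break"}.
#' @slot heightLoss absolute height loss in pixels (wedge/biconcave/crush).
#' @slot offset step-off displacement in pixels.
#' @slot gapLen cortical break fissure depth in pixels.
#' @slot acute logical truth flag for the vertebra.
#' @exportClass DeformitySpec
setClass("DeformitySpec",
  representation(level = "integer", kind = "character",
                 heightLoss = "numeric", offset = "numeric",
                 gapLen = "numeric", acute = "logical"),
  prototype(level = 1L, kind = "wedge", heightLoss = 0,
            offset = 0, gapLen = 0, acute = FALSE))

setValidity("DeformitySpec", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% DEFORMITY_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(DEFORMITY_KINDS, collapse = ", ")))
  if (length(object@level) != 1L || is.na(object@level) || object@level < 1L)
    msg <- c(msg, "level must be a positive integer")
  if (object@heightLoss < 0) msg <- c(msg, "heightLoss must be >= 0")
  if (object@offset < 0) msg <- c(msg, "offset must be >= 0")
  if (object@gapLen < 0) msg <- c(msg, "gapLen must be >= 0")
  if (object@kind %in% ACUTE_MARKER_KINDS && !isTRUE(object@acute))
    msg <- c(msg, sprintf("kind '%s' is an acute marker and requires acute = TRUE",
                          object@kind))
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of a sagittal spine phantom
#'
#' Generative parameters for a stack of trapezoidal vertebral bodies in a
#' 2D sagittal raster. Coordinates are 0-based with y increasing downward;
#' anterior is left, superior is top. Level 1 is the topmost (smallest) body
#' and per-level linear scale grows by \code{sizeGradient} per level, so lower
#' (lumbar-like) bodies are larger.
#'
#' @slot nLevels number of vertebral bodies (1--12).
#' @slot baseWidth anterior--posterior extent of the topmost body, pixels.
#' @slot baseHeight posterior height of the topmost body, pixels.
#' @slot sizeGradient multiplicative per-level scale factor (> 0).
#' @slot gap inter-body spacing in pixels.
#' @slot wedgingProfile per-level signed physiological wedging fraction w;
#'   anterior height = posterior height * (1 - w). Negative w makes the
#'   posterior side lower (the physiological pattern of the lowest lumbar
#'   levels).
#' @slot deformities list of \linkS4class{DeformitySpec}.
#' @slot noiseSigma boundary-jitter standard deviation in pixels.
#' @slot seed integer random seed for the jitter.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(nLevels = "integer", baseWidth = "numeric",
                 baseHeight = "numeric", sizeGradient = "numeric",
                 gap = "numeric", wedgingProfile = "numeric",
                 deformities = "list", noiseSigma = "numeric",
                 seed = "integer"),
  prototype(nLevels = 6L, baseWidth = 60, baseHeight = 36,
            sizeGradient = 1.06, gap = 6, wedgingProfile = numeric(),
            deformities = list(), noiseSigma = 0, seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@nLevels < 1L || object@nLevels > 12L)
    msg <- c(msg, "nLevels must be in 1..12")
  if (object@baseHeight <= 0) msg <- c(msg, "baseHeight must be > 0")
  if (object@baseWidth <= 0) msg <- c(msg, "baseWidth must be > 0")
  if (object@sizeGradient <= 0) msg <- c(msg, "sizeGradient must be > 0")
  if (object@gap < 0) msg <- c(msg, "gap must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(object@wedgingProfile) &&
      length(object@wedgingProfile) != object@nLevels)
    msg <- c(msg, "wedgingProfile must have one entry per level (or be empty)")
  if (length(object@wedgingProfile) && any(abs(object@wedgingProfile) >= 1))
    msg <- c(msg, "wedgingProfile entries must be in (-1, 1)")
  for (d in object@deformities) {
    if (!is(d, "DeformitySpec")) {
      msg <- c(msg, "deformities must be DeformitySpec objects")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' SpinePhantom: generative ground truth for a synthetic spine
#'
#' Produced by \code{\link{buildPhantom}}. Holds one closed polygon per
#' vertebral body (image coordinates, columns x/y), the exact generative
#' anterior/middle/posterior heights, the per-vertebra acute truth flags, and
#' the \linkS4class{PhantomSpec} that generated it.
#'
#' @slot polygons list of n x 2 numeric matrices (columns x, y), one per level.
#' @slot trueHeights numeric matrix (levels x 3) with columns ha, hm, hp.
#' @slot truthAcute logical vector, one flag per level.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @exportClass SpinePhantom
setClass("SpinePhantom",
  representation(polygons = "list", trueHeights = "matrix",
                 truthAcute = "logical", spec = "PhantomSpec"))

setValidity("SpinePhantom", function(object) {
  msg <- character()
  n <- length(object@polygons)
  if (nrow(object@trueHeights) != n || length(object@truthAcute) != n)
    msg <- c(msg, "one polygon, height triple and truth flag per level required")
  if (ncol(object@trueHeights) != 3L)
    msg <- c(msg, "trueHeights must have columns ha, hm, hp")
  if (any(object@trueHeights <= 0))
    msg <- c(msg, "trueHeights must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' MeasurementConfig: height-measurement parameters
#'
#' @slot samplingFractions three strictly increasing fractions in (0,1) of the
#'   anterior--posterior chord at which heights are read (anterior, middle,
#'   posterior).
#' @slot axisMethod \code{"principal_axis"} (rotate each body to its principal
#'   axis before reading vertical extents) or \code{"bounding_box"}.
#' @slot hlrVariant \code{"printed"} for
#'   (1 - min(ha, hm)/hp) * 100, or \code{"min_over_max"} for
#'   (1 - min(ha, hm, hp)/max(ha, hm, hp)) * 100.
#' @slot bandWidth band half-width as a fraction of the AP extent is
#'   \code{bandWidth / 2}; heights are averaged over the band.
#' @exportClass MeasurementConfig
setClass("MeasurementConfig",
  representation(samplingFractions = "numeric", axisMethod = "character",
                 hlrVariant = "character", bandWidth = "numeric"),
  prototype(samplingFractions = c(0.10, 0.50, 0.90),
            axisMethod = "principal_axis", hlrVariant = "printed",
            bandWidth = 0.05))

setValidity("MeasurementConfig", function(object) {
  msg <- character()
  f <- object@samplingFractions
  if (length(f) != 3L || any(f <= 0) || any(f >= 1) || any(diff(f) <= 0))
    msg <- c(msg, "samplingFractions must be three strictly increasing values in (0,1)")
  if (!object@axisMethod %in% c("principal_axis", "bounding_box"))
    msg <- c(msg, "axisMethod must be 'principal_axis' or 'bounding_box'")
  if (!object@hlrVariant %in% c("printed", "min_over_max"))
    msg <- c(msg, "hlrVariant must be 'printed' or 'min_over_max'")
  if (object@bandWidth <= 0 || object@bandWidth >= 0.5)
    msg <- c(msg, "bandWidth must be in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: vertebra-wise 2x2 counts
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer"),
  prototype(tp = 0L, fp = 0L, tn = 0L, fn = 0L))

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(counts)) || any(counts < 0L))
    "tp, fp, tn, fn must be non-negative counts"
  else TRUE
})

#' ROCCurve: threshold sweep of a score-based detector
#'
#' @slot points data.frame with columns threshold, fpr, tpr, ordered by
#'   nondecreasing fpr, including the (0,0) and (1,1) endpoints.
#' @slot auc trapezoidal area under the curve, in [0,1].
#' @exportClass ROCCurve
setClass("ROCCurve",
  representation(points = "data.frame", auc = "numeric"))

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (!all(c("fpr", "tpr") %in% names(object@points)))
    msg <- c(msg, "points must have fpr and tpr columns")
  else if (is.unsorted(object@points$fpr))
    msg <- c(msg, "points must be ordered by nondecreasing fpr")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  if (length(msg)) msg else TRUE
})
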