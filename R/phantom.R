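# Synthetic sagittal spine phantoms.
#
# Geometry convention (fixed once for the whole package): 0-based image
# coordinates, row-major, y increases downward; anterior = left, superior =
# top. Each vertebral body is an isosceles trapezoid with a flat inferior
# endplate; deformities act on the superior endplate.

# Fractions of the AP chord at which the generative heights are anchored.
# These match the default measurement sampling fractions, so generative and
# measured heights are directly comparable.
HEIGHT_ANCHORS <- c(0.10, 0.50, 0.90)

# Plateau breakpoints of the deformity depression profiles. Each profile is
# piecewise linear with plateaus covering the measurement bands around the
# height anchors, so deformities change the generative heights exactly.
DEPRESSION_KNOTS <- c(0, 0.15, 0.45, 0.55, 0.85, 1)

# Step-off placement: displaced stretch of the superior endplate, as
# fractions of the AP chord. Chosen between the anterior and middle height
# anchors so the step perturbs the cortex without altering anchored heights.
STEP_SPAN <- c(0.16, 0.44)

# Cortical break fissure: AP position (fraction) and full width in pixels.
BREAK_POS <- 0.68
BREAK_WIDTH <- 2

PHANTOM_MARGIN <- 8

#' Construct a DeformitySpec
#'
#' @param level target vertebra index (1 = topmost body).
#' @param kind \code{"wedge"}, \code{"biconcave"}, \code{"crush"},
#'   \code{"step_off"} or \code{"cortical_break"}.
#' @param heightLoss absolute height loss in pixels (wedge/biconcave/crush).
#' @param offset step-off displacement in pixels.
#' @param gapLen cortical break fissure depth in pixels.
#' @param acute truth flag; \code{step_off} and \code{cortical_break} are
#'   acute markers and default to (and require) \code{TRUE}.
#' @return a \linkS4class{DeformitySpec}.
#' @examples
#' deformitySpec(1, "wedge", heightLoss = 5)
#' deformitySpec(2, "step_off", offset = 4)
#' @export
deformitySpec <- function(level, kind, heightLoss = 0, offset = 0, gapLen = 0,
                          acute = kind %in% ACUTE_MARKER_KINDS) {
  new("DeformitySpec", level = as.integer(level), kind = kind,
      heightLoss = heightLoss, offset = offset, gapLen = gapLen,
      acute = acute)
}

#' Construct a PhantomSpec
#'
#' Defaults give a mid-sized six-level spine with no deformities and no
#' boundary jitter. See \linkS4class{PhantomSpec} for slot meanings.
#'
#' @param nLevels number of vertebral bodies (1--12).
#' @param baseWidth,baseHeight AP extent and posterior height of the topmost
#'   body, pixels.
#' @param sizeGradient per-level multiplicative scale (> 0).
#' @param gap inter-body spacing, pixels.
#' @param wedgingProfile per-level signed wedging fraction (empty = none).
#' @param deformities list of \code{\link{deformitySpec}} objects.
#' @param noiseSigma vertex jitter SD, pixels.
#' @param seed integer seed for the jitter.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(nLevels = 5, deformities = list(deformitySpec(3, "wedge", 10)))
#' @export
phantomSpec <- function(nLevels = 6L, baseWidth = 60, baseHeight = 36,
                        sizeGradient = 1.06, gap = 6,
                        wedgingProfile = numeric(), deformities = list(),
                        noiseSigma = 0, seed = 1L) {
  new("PhantomSpec", nLevels = as.integer(nLevels), baseWidth = baseWidth,
      baseHeight = baseHeight, sizeGradient = sizeGradient, gap = gap,
      wedgingProfile = as.numeric(wedgingProfile), deformities = deformities,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

# Depression depth (pixels) at AP fraction t for one deformity.
depressionProfile <- function(kind, loss, t) {
  vals <- switch(kind,
    wedge     = c(loss, loss, loss / 2, loss / 2, 0, 0),
    biconcave = c(0, 0, loss, loss, 0, 0),
    crush     = rep(loss, 6),
    return(rep(0, length(t))))
  stats::approx(DEPRESSION_KNOTS, vals, xout = t, rule = 2)$y
}

#' Build a spine phantom from its spec
#'
#' Realizes the generative geometry: one trapezoidal body per level (scaled by
#' \code{sizeGradient^(level-1)}, wedged per \code{wedgingProfile}), with
#' deformities applied to the superior endplate. Wedge, biconcave and crush
#' deformities subtract \code{heightLoss} from the anterior, middle, or all
#' three generative heights exactly; step-offs and cortical breaks perturb the
#' boundary polyline between the height anchors without changing the
#' generative heights.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{SpinePhantom} with exact generative heights (read at
#'   the 10/50/90\% AP anchors) and acute truth flags.
#' @examples
#' ph <- buildPhantom(phantomSpec(nLevels = 1, baseHeight = 21, baseWidth = 60,
#'   deformities = list(deformitySpec(1, "wedge", heightLoss = 5, acute = FALSE))))
#' trueHeights(ph)  # 16, 18.5, 21
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  n <- spec@nLevels
  for (d in spec@deformities) {
    validObject(d)
    if (d@level > n)
      stop(sprintf("deformity level %d out of range (phantom has %d levels)",
                   d@level, n))
  }
  scales <- spec@sizeGradient^(seq_len(n) - 1)
  widths <- spec@baseWidth * scales
  hps <- spec@baseHeight * scales
  wed <- if (length(spec@wedgingProfile)) spec@wedgingProfile else rep(0, n)
  has <- hps * (1 - wed)

  defsByLevel <- split(spec@deformities,
                       vapply(spec@deformities, function(d) d@level, 1L))

  polys <- vector("list", n)
  heights <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("ha", "hm", "hp")))
  acute <- logical(n)
  yTop <- PHANTOM_MARGIN

  for (k in seq_len(n)) {
    maxh <- max(has[k], hps[k])
    yBot <- yTop + maxh
    x0 <- PHANTOM_MARGIN
    w <- widths[k]
    hBase <- function(t) has[k] + t * (hps[k] - has[k])

    defs <- defsByLevel[[as.character(k)]]
    if (is.null(defs)) defs <- list()
    dep <- function(t) {
      d <- rep(0, length(t))
      for (df in defs)
        if (df@kind %in% c("wedge", "biconcave", "crush"))
          d <- d + depressionProfile(df@kind, df@heightLoss, t)
      d
    }
    h <- function(t) hBase(t) - dep(t)

    heights[k, ] <- h(HEIGHT_ANCHORS)
    acute[k] <- any(vapply(defs, function(d) isTRUE(d@acute), TRUE))
    if (any(h(c(0, DEPRESSION_KNOTS, 1)) <= 0))
      stop(sprintf("level %d: height loss exceeds body height", k))

    stepOff <- Filter(function(d) d@kind == "step_off", defs)
    breaks <- Filter(function(d) d@kind == "cortical_break", defs)

    # top edge knots, walked posterior (t = 1) to anterior (t = 0)
    tKnots <- sort(unique(c(0, 1, DEPRESSION_KNOTS)), decreasing = TRUE)
    topPts <- cbind(x = x0 + tKnots * w, y = yBot - h(tKnots))

    if (length(stepOff)) {
      off <- stepOff[[1]]@offset
      sel <- topPts[, "x"] > x0 + STEP_SPAN[1] * w &
             topPts[, "x"] < x0 + STEP_SPAN[2] * w
      topPts[sel, "y"] <- topPts[sel, "y"] + off
      xs <- x0 + STEP_SPAN * w
      # vertical jumps at both ends of the displaced stretch
      right <- cbind(x = c(xs[2], xs[2]),
                     y = yBot - h(STEP_SPAN[2]) + c(0, off))
      left <- cbind(x = c(xs[1], xs[1]),
                    y = yBot - h(STEP_SPAN[1]) + c(off, 0))
      keepHi <- topPts[, "x"] >= xs[2]
      keepMid <- sel
      keepLo <- topPts[, "x"] <= xs[1]
      topPts <- rbind(topPts[keepHi, , drop = FALSE], right,
                      topPts[keepMid, , drop = FALSE], left,
                      topPts[keepLo, , drop = FALSE])
    }

    if (length(breaks)) {
      gl <- breaks[[1]]@gapLen
      xb <- x0 + BREAK_POS * w
      hw <- BREAK_WIDTH / 2
      yb <- yBot - h(BREAK_POS)
      if (gl >= h(BREAK_POS))
        stop(sprintf("level %d: break gapLen exceeds body height", k))
      notch <- cbind(x = c(xb + hw, xb + hw, xb - hw, xb - hw),
                     y = c(yb, yb + gl, yb + gl, yb))
      before <- topPts[topPts[, "x"] > xb + hw, , drop = FALSE]
      after <- topPts[topPts[, "x"] < xb - hw, , drop = FALSE]
      topPts <- rbind(before, notch, after)
    }

    verts <- rbind(cbind(x = x0, y = yBot), cbind(x = x0 + w, y = yBot),
                   topPts)
    # drop duplicated consecutive vertices
    keep <- c(TRUE, rowSums(abs(diff(verts))) > 1e-9)
    verts <- verts[keep, , drop = FALSE]

    polys[[k]] <- unname(verts)
    yTop <- yBot + spec@gap
  }

  if (spec@noiseSigma > 0) {
    polys <- withSeed(spec@seed, lapply(polys, function(p) {
      p + matrix(stats::rnorm(length(p), 0, spec@noiseSigma), nrow(p), 2)
    }))
  }

  new("SpinePhantom", polygons = polys, trueHeights = heights,
      truthAcute = acute, spec = spec)
}

#' Rasterize polygons into a label mask
#'
#' A pixel gets label \code{k} iff its center lies strictly inside polygon
#' \code{k} (no anti-aliasing). Pixel \code{(i, j)} of the returned matrix
#' (row i, column j, 1-based) covers the unit square with center
#' \code{(x = j - 0.5, y = i - 0.5)} in the 0-based geometry convention.
#'
#' @param polys list of closed polygons (n x 2 matrices, columns x, y).
#' @param dim canvas size \code{c(rows, cols)}; defaults to the polygon
#'   extent plus a margin.
#' @param supersample scale factor applied to all coordinates (and the
#'   canvas) before rasterization.
#' @return integer matrix; 0 = background, k = index of the covering polygon.
#' @examples
#' rect <- cbind(x = c(2, 22, 22, 2), y = c(3, 3, 13, 13))
#' sum(rasterizeMask(list(rect)) == 1L)  # 200 pixels
#' @export
rasterizeMask <- function(polys, dim = NULL, supersample = 1) {
  stopifnot(supersample >= 1)
  polys <- lapply(polys, function(p) p * supersample)
  if (is.null(dim)) {
    maxX <- max(vapply(polys, function(p) max(p[, 1]), 1))
    maxY <- max(vapply(polys, function(p) max(p[, 2]), 1))
    dim <- ceiling(c(maxY, maxX) + PHANTOM_MARGIN * supersample)
  }
  mask <- matrix(0L, dim[1], dim[2])
  for (k in seq_along(polys)) {
    p <- polys[[k]]
    if (any(p[, 1] < 0) || any(p[, 2] < 0) ||
        any(p[, 1] > dim[2]) || any(p[, 2] > dim[1]))
      stop("polygon does not fit in the target canvas")
    rows <- max(1L, floor(min(p[, 2]))):min(dim[1], ceiling(max(p[, 2])))
    cols <- max(1L, floor(min(p[, 1]))):min(dim[2], ceiling(max(p[, 1])))
    cx <- rep(cols - 0.5, each = length(rows))
    cy <- rep(rows - 0.5, times = length(cols))
    inside <- pracma::inpolygon(cx, cy, p[, 1], p[, 2], boundary = FALSE)
    if (!any(inside)) next
    idx <- cbind(row = rep(rows, times = length(cols))[inside],
                 col = rep(cols, each = length(rows))[inside])
    if (any(mask[idx] != 0L)) stop("overlapping polygons")
    mask[idx] <- k
  }
  mask
}

#' Rasterize a spine phantom
#'
#' @param phantom a \linkS4class{SpinePhantom}.
#' @param supersample resolution multiplier (>= 1); heights and widths in the
#'   mask scale by this factor.
#' @param dim optional canvas size \code{c(rows, cols)} after supersampling.
#' @return integer label mask (see \code{\link{rasterizeMask}}).
#' @export
rasterizePhantom <- function(phantom, supersample = 1, dim = NULL) {
  rasterizeMask(polygons(phantom), dim = dim, supersample = supersample)
}

#' Emulate a binary vertebra detector with fixed operating point
#'
#' Stand-in for a trained detector: each truly acute vertebra is called
#' positive with probability \code{sens}, each normal vertebra with
#' probability \code{1 - spec}; draws are independent and reproducible under
#' a fixed seed. The confidence score is derived from the underlying uniform
#' draw (score = 1 - u), so higher scores are more confidently positive; the
#' emulator realizes one fixed operating point per class rather than a single
#' global score threshold.
#'
#' @param truthAcute logical vector of per-vertebra truth flags.
#' @param sens,spec target sensitivity and specificity in [0, 1].
#' @param seed integer seed.
#' @return data.frame with columns \code{level}, \code{positive}, \code{score}.
#' @examples
#' emulateDetector(c(TRUE, FALSE, TRUE), sens = 1, spec = 1, seed = 1)
#' @export
emulateDetector <- function(truthAcute, sens, spec, seed = 1L) {
  stopifnot(is.logical(truthAcute), sens >= 0, sens <= 1,
            spec >= 0, spec <= 1)
  n <- length(truthAcute)
  u <- withSeed(seed, stats::runif(n))
  score <- 1 - u
  positive <- ifelse(truthAcute, u < sens, u < 1 - spec)
  data.frame(level = seq_len(n), positive = positive, score = score)
}

#' Sample a cohort of phantom specs
#'
#' Draws a cohort of synthetic spines emulating a screening test set: 5--8
#' vertebral bodies per spine, mild physiological wedging at the lowest
#' levels, a configurable fraction of acute vertebrae (default matches a
#' 148/1030 class balance) carrying a step-off or cortical-break marker with
#' variable height loss, plus a fraction of chronic (non-acute) wedge or
#' biconcave deformities whose height loss alone can cross the Genant
#' thresholds (the false-positive substrate for height-based screening).
#'
#' @param nSpines number of spines.
#' @param acuteRate per-vertebra probability of an acute fracture.
#' @param chronicRate per-vertebra probability of a chronic deformity.
#' @param levelRange integer range of levels per spine.
#' @param seed integer seed.
#' @return list of \linkS4class{PhantomSpec}.
#' @export
sampleCohortSpecs <- function(nSpines, acuteRate = 148 / 1030,
                              chronicRate = 0.08, levelRange = c(5L, 8L),
                              seed = 1L) {
  withSeed(seed, {
    lapply(seq_len(nSpines), function(i) {
      lv <- seq(levelRange[1], levelRange[2])
      n <- lv[sample.int(length(lv), 1)]
      wedging <- rep(0, n)
      wedging[n] <- -0.08          # posterior slightly lower at the lowest level
      if (n > 1) wedging[n - 1] <- -0.04
      defs <- list()
      for (k in seq_len(n)) {
        r <- stats::runif(1)
        if (r < acuteRate) {
          base <- sample(c("wedge", "biconcave", "crush"), 1)
          loss <- stats::runif(1, 0.10, 0.45) * 36 * 1.06^(k - 1)
          marker <- sample(ACUTE_MARKER_KINDS, 1)
          defs <- c(defs, deformitySpec(k, base, heightLoss = loss, acute = TRUE))
          defs <- c(defs, if (marker == "step_off")
            deformitySpec(k, "step_off", offset = stats::runif(1, 3, 6))
          else
            deformitySpec(k, "cortical_break", gapLen = stats::runif(1, 4, 8)))
        } else if (r < acuteRate + chronicRate) {
          base <- sample(c("wedge", "biconcave"), 1)
          loss <- stats::runif(1, 0.20, 0.42) * 36 * 1.06^(k - 1)
          defs <- c(defs, deformitySpec(k, base, heightLoss = loss,
                                        acute = FALSE))
        }
      }
      phantomSpec(nLevels = n, wedgingProfile = wedging, deformities = defs,
                  seed = sample.int(.Machine$integer.max %/% 2, 1))
    })
  })
}
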