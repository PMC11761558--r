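# Preprocessing stages: Hounsfield-unit windowing, cortical contour
# extraction, and per-vertebra patch standardization (crop, contrast, resize).

#' Apply CT windowing
#'
#' Linear map of the HU interval [level - width/2, level + width/2] onto
#' [0, 1], clamped outside. The default (level 300, width 850) is a bone-type
#' display window.
#'
#' @param hu numeric matrix (or vector) of Hounsfield units.
#' @param level window level (center), HU.
#' @param width window width (span), HU; must be > 0.
#' @return values in [0, 1], same shape as \code{hu}.
#' @examples
#' applyWindow(c(-125, 87.5, 300, 725))  # 0 0.25 0.5 1
#' @export
applyWindow <- function(hu, level = 300, width = 850) {
  stopifnot(width > 0)
  pmin(pmax((hu - (level - width / 2)) / width, 0), 1)
}

#' Extract the cortical contour of one vertebra
#'
#' Returns the boundary pixels of the label: pixels carrying
#' \code{vertebraId} with at least one 8-neighbor (or image border) that does
#' not carry it. Interior pixels are removed. 8-connectivity keeps diagonal
#' cortices unbroken.
#'
#' @param mask integer label mask.
#' @param vertebraId label whose contour to extract.
#' @return binary integer matrix of the same size; 1 = contour pixel.
#' @examples
#' m <- matrix(0L, 14, 14); m[3:12, 3:12] <- 1L
#' sum(extractContour(m, 1))  # 36
#' @export
extractContour <- function(mask, vertebraId) {
  if (!any(mask == vertebraId))
    stop(sprintf("label %s absent from mask", format(vertebraId)))
  bin <- mask == vertebraId
  nr <- nrow(bin); nc <- ncol(bin)
  # pad with background so border pixels count as boundary
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- bin
  allNb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    allNb <- allNb & pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out <- matrix(0L, nr, nc)
  out[bin & !allNb] <- 1L
  out
}

# Keys cubic-convolution kernel, a = -0.5 (Catmull-Rom): reproduces linear
# ramps exactly and matches the common bicubic resampling definition.
cubicKernel <- function(t) {
  t <- abs(t)
  a <- -0.5
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Separable bicubic resize with clamped edges.
resizeBicubic <- function(x, outDim) {
  resize1d <- function(m, nOut) {  # resample columns of m to nOut rows
    nIn <- nrow(m)
    src <- ((seq_len(nOut) - 0.5) * nIn / nOut) - 0.5   # 0-based sample pos
    i0 <- floor(src)
    out <- matrix(0, nOut, ncol(m))
    wsum <- numeric(nOut)
    for (k in -1:2) {
      idx <- pmin(pmax(i0 + k, 0), nIn - 1) + 1
      w <- cubicKernel(src - (i0 + k))
      out <- out + m[idx, , drop = FALSE] * w
      wsum <- wsum + w
    }
    out / wsum
  }
  x <- resize1d(x, outDim[1])
  t(resize1d(t(x), outDim[2]))
}

#' Crop a patch and standardize it for classification
#'
#' Crops the half-open, 0-based bounding box \code{[r0, r1) x [c0, c1)},
#' applies a mean-anchored linear contrast stretch with clamping
#' (out = mean + factor * (in - mean), clamped to [0, 1]), and resizes to
#' \code{outSize} by bicubic interpolation.
#'
#' @param image numeric matrix with values in [0, 1].
#' @param bbox integer vector \code{c(r0, c0, r1, c1)}, 0-based, half-open.
#' @param contrastFactor contrast multiplier about the patch mean (default 2).
#' @param outSize output size \code{c(rows, cols)}, default \code{c(224, 224)}.
#' @return numeric matrix of size \code{outSize} with values in [0, 1].
#' @examples
#' img <- matrix(0.5, 64, 64)
#' dim(cropAndStandardize(img, c(0, 0, 64, 64)))  # 224 224
#' @export
cropAndStandardize <- function(image, bbox, contrastFactor = 2,
                               outSize = c(224, 224)) {
  r0 <- bbox[1]; c0 <- bbox[2]; r1 <- bbox[3]; c1 <- bbox[4]
  if (r1 <= r0 || c1 <= c0) stop("empty bounding box")
  if (r0 < 0 || c0 < 0 || r1 > nrow(image) || c1 > ncol(image))
    stop("bounding box outside image")
  patch <- image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  m <- mean(patch)
  patch <- pmin(pmax(m + contrastFactor * (patch - m), 0), 1)
  pmin(pmax(resizeBicubic(patch, outSize), 0), 1)  # bicubic can overshoot
}
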