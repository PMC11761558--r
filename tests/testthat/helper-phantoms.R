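# Shared fixtures, all generated in code.

# Single-body mask with one optional deformity.
singleBodyMask <- function(kind = NULL, h = 36, w = 60, loss = 0, offset = 0,
                           gapLen = 0, wedging = numeric(), supersample = 1,
                           acute = kind %in% c("step_off", "cortical_break")) {
  defs <- if (is.null(kind)) list() else
    list(deformitySpec(1, kind, heightLoss = loss, offset = offset,
                       gapLen = gapLen, acute = acute))
  ph <- buildPhantom(phantomSpec(nLevels = 1, baseHeight = h, baseWidth = w,
                                 wedgingProfile = wedging, deformities = defs))
  rasterizePhantom(ph, supersample = supersample)
}

# Rotate a polygon by `deg` about its centroid and translate to `at`.
rotatePoly <- function(poly, deg, at = c(0, 0)) {
  th <- deg * pi / 180
  R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  ctr <- colMeans(poly)
  sweep(sweep(poly, 2, ctr) %*% R, 2, at, "+")
}

# Build an aligned truth/calls pair realizing given confusion counts.
# Acute vertebrae occupy indices 1..nAcute.
callsFromCounts <- function(tp, fp, nAcute = 148, nNormal = 882) {
  n <- nAcute + nNormal
  positive <- rep(FALSE, n)
  if (tp > 0) positive[seq_len(tp)] <- TRUE
  if (fp > 0) positive[nAcute + seq_len(fp)] <- TRUE
  data.frame(level = seq_len(n), positive = positive)
}

cohortTruth <- function(nAcute = 148, nNormal = 882) {
  c(rep(TRUE, nAcute), rep(FALSE, nNormal))
}

# Two call sets with prescribed marginal TP/FP counts and intersection
# overlap (tpBoth true positives and fpBoth false positives shared).
overlappingCalls <- function(tpA, fpA, tpB, fpB, tpBoth, fpBoth,
                             nAcute = 148, nNormal = 882) {
  stopifnot(tpBoth <= min(tpA, tpB), fpBoth <= min(fpA, fpB),
            tpA + tpB - tpBoth <= nAcute, fpA + fpB - fpBoth <= nNormal)
  n <- nAcute + nNormal
  posA <- rep(FALSE, n); posB <- rep(FALSE, n)
  posA[seq_len(tpA)] <- TRUE
  posB[seq_len(tpBoth)] <- TRUE                       # shared TPs
  if (tpB > tpBoth) posB[tpA + seq_len(tpB - tpBoth)] <- TRUE
  posA[nAcute + seq_len(fpA)] <- TRUE
  posB[nAcute + seq_len(fpBoth)] <- TRUE              # shared FPs
  if (fpB > fpBoth) posB[nAcute + fpA + seq_len(fpB - fpBoth)] <- TRUE
  list(a = data.frame(level = seq_len(n), positive = posA),
       b = data.frame(level = seq_len(n), positive = posB))
}

# Printed vertebra-wise confusion counts of the evaluated cohort
# (148 acute / 882 normal), per method.
PRINTED_COUNTS <- list(
  hlr       = c(tp = 102, fp = 82, tn = 800, fn = 46),
  eevd      = c(tp = 100, fp = 7,  tn = 875, fn = 48),
  tsvd_sd   = c(tp = 125, fp = 28, tn = 854, fn = 23),
  tsvd_dc   = c(tp = 115, fp = 24, tn = 858, fn = 33),
  or_eevd   = c(tp = 120, fp = 87, tn = 795, fn = 28),
  or_sd     = c(tp = 130, fp = 98, tn = 784, fn = 18),
  or_dc     = c(tp = 126, fp = 94, tn = 788, fn = 22),
  and_eevd  = c(tp = 82,  fp = 2,  tn = 880, fn = 66),
  and_sd    = c(tp = 97,  fp = 12, tn = 870, fn = 51),
  and_dc    = c(tp = 91,  fp = 12, tn = 870, fn = 57))

# Published metric values (percent, 2 decimals) per method:
# sensitivity, specificity, accuracy, precision.
PRINTED_METRICS <- list(
  hlr      = c(68.92, 90.70, 87.57, 55.43),
  eevd     = c(67.57, 99.21, 94.66, 93.46),
  tsvd_sd  = c(84.46, 96.83, 95.05, 81.70),
  tsvd_dc  = c(77.70, 97.28, 94.47, 82.73),
  or_eevd  = c(81.08, 90.14, 88.83, 57.97),
  or_sd    = c(87.84, 88.89, 88.74, 57.02),
  or_dc    = c(85.14, 89.34, 88.74, 57.27),
  and_eevd = c(55.41, 99.77, 93.40, 97.62),
  and_sd   = c(65.54, 98.64, 93.88, 88.99),
  and_dc   = c(61.49, 98.64, 93.30, 88.35))

# Detector-pair overlaps with the height-based (HLR) calls: shared TPs / FPs.
PRINTED_OVERLAPS <- list(
  eevd    = c(tpBoth = 82, fpBoth = 2),
  tsvd_sd = c(tpBoth = 97, fpBoth = 12),
  tsvd_dc = c(tpBoth = 91, fpBoth = 12))
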