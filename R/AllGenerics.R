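#' Accessors for phantom and evaluation objects
#'
#' \code{polygons}, \code{trueHeights}, \code{truthAcute} and \code{phantomSpec}
#' read the slots of a \linkS4class{SpinePhantom}; \code{counts} returns the
#' four cells of a \linkS4class{ConfusionMatrix} as a named integer vector;
#' \code{auc} returns the area under a \linkS4class{ROCCurve};
#' \code{rocPoints} its (threshold, fpr, tpr) table.
#'
#' @param x the object.
#' @return the slot value (see Details of each class).
#' @name accessors
#' @aliases polygons trueHeights truthAcute counts auc rocPoints
NULL

#' @rdname accessors
#' @export
setGeneric("polygons", function(x) standardGeneric("polygons"))

#' @rdname accessors
#' @export
setGeneric("trueHeights", function(x) standardGeneric("trueHeights"))

#' @rdname accessors
#' @export
setGeneric("truthAcute", function(x) standardGeneric("truthAcute"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname accessors
setMethod("polygons", "SpinePhantom", function(x) x@polygons)

#' @rdname accessors
setMethod("trueHeights", "SpinePhantom", function(x) x@trueHeights)

#' @rdname accessors
setMethod("truthAcute", "SpinePhantom", function(x) x@truthAcute)

#' @rdname accessors
setMethod("counts", "ConfusionMatrix", function(x)
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn))

#' @rdname accessors
setMethod("auc", "ROCCurve", function(x) x@auc)

#' @rdname accessors
setMethod("rocPoints", "ROCCurve", function(x) x@points)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d level(s), base %gx%g px, gradient %.3f, gap %g px\n",
              object@nLevels, object@baseWidth, object@baseHeight,
              object@sizeGradient, object@gap))
  cat(sprintf("  deformities: %d, noiseSigma: %g, seed: %d\n",
              length(object@deformities), object@noiseSigma, object@seed))
})

setMethod("show", "DeformitySpec", function(object) {
  cat(sprintf("DeformitySpec: level %d, kind %s, loss %g, offset %g, gap %g, acute %s\n",
              object@level, object@kind, object@heightLoss, object@offset,
              object@gapLen, object@acute))
})

setMethod("show", "SpinePhantom", function(object) {
  cat(sprintf("SpinePhantom: %d vertebral bodies, %d acute\n",
              length(object@polygons), sum(object@truthAcute)))
  h <- object@trueHeights
  cat(sprintf("  posterior heights %.1f-%.1f px\n", min(h[, 3]), max(h[, 3])))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (vertebra-wise)\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("acute", "normal"),
                              call = c("positive", "negative")))
  print(m)
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d points, AUC = %.4f\n",
              nrow(object@points), object@auc))
})
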