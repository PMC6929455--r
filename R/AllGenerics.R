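#' @include AllClasses.R
NULL

#' Accessors for fitted factorizations and fixtures
#'
#' `latentFactors()` returns the [FactorPair-class]; `latentA()` /
#' `latentB()` the individual factor matrices; `objectiveTrace()` the
#' per-iteration objective values; `aucMean()`, `aucSd()`,
#' `perRepeatAuc()` the cross-validation summaries; `heldOut()` the masked
#' pairs of a planted fixture; `cloudPoints()` the coordinate matrix of a
#' line-cloud fixture.
#'
#' @param x the object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("latentFactors", function(x) standardGeneric("latentFactors"))
#' @rdname accessors
#' @export
setGeneric("latentA", function(x) standardGeneric("latentA"))
#' @rdname accessors
#' @export
setGeneric("latentB", function(x) standardGeneric("latentB"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("aucMean", function(x) standardGeneric("aucMean"))
#' @rdname accessors
#' @export
setGeneric("aucSd", function(x) standardGeneric("aucSd"))
#' @rdname accessors
#' @export
setGeneric("perRepeatAuc", function(x) standardGeneric("perRepeatAuc"))
#' @rdname accessors
#' @export
setGeneric("heldOut", function(x) standardGeneric("heldOut"))
#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname accessors
#' @export
setMethod("latentFactors", "RcmfFit", function(x) x@factors)
#' @rdname accessors
#' @export
setMethod("latentA", "FactorPair", function(x) x@A)
#' @rdname accessors
#' @export
setMethod("latentA", "RcmfFit", function(x) x@factors@A)
#' @rdname accessors
#' @export
setMethod("latentB", "FactorPair", function(x) x@B)
#' @rdname accessors
#' @export
setMethod("latentB", "RcmfFit", function(x) x@factors@B)
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "RcmfFit", function(x) x@objectiveTrace)
#' @rdname accessors
#' @export
setMethod("aucMean", "CvResult", function(x) x@aucMean)
#' @rdname accessors
#' @export
setMethod("aucSd", "CvResult", function(x) x@aucSd)
#' @rdname accessors
#' @export
setMethod("perRepeatAuc", "CvResult", function(x) x@perRepeatAuc)
#' @rdname accessors
#' @export
setMethod("heldOut", "PlantedInstance", function(x) x@heldOut)
#' @rdname accessors
#' @export
setMethod("cloudPoints", "LineCloud", function(x) x@points)

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d entities\n", nrow(object)))
  cat(sprintf("  mean off-diagonal similarity %.4f\n",
              mean(object@.Data[row(object@.Data) != col(object@.Data)])))
})

setMethod("show", "AssociationMatrix", function(object) {
  x <- object@.Data
  cat(sprintf("AssociationMatrix: %d miRNAs x %d diseases%s\n",
              nrow(x), ncol(x), if (object@predicted) " (predicted scores)" else ""))
  if (!object@predicted)
    cat(sprintf("  %d known associations (density %.3f)\n",
                sum(x == 1), mean(x == 1)))
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG: %d terms, %d child->parent edges\n",
              length(object@terms), nrow(object@edges)))
})

setMethod("show", "RcmfFit", function(object) {
  tr <- object@objectiveTrace
  cat(sprintf("%s fit: k = %d, %d iterations (%s), objective %.6g -> %.6g\n",
              object@config@variant, object@factors@k, object@iterationsRun,
              if (object@converged) "converged" else "max iterations",
              tr[1], tr[length(tr)]))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: AUC %.4f(%.4f) over %d x %d-fold CV-p\n",
              object@aucMean, object@aucSd, object@plan@nRepeats,
              object@plan@nFolds))
})

setMethod("show", "PlantedInstance", function(object) {
  cat(sprintf("PlantedInstance: %d x %d, %d masked positives, seed %d\n",
              nrow(object@Y), ncol(object@Y), nrow(object@heldOut),
              object@seed))
})

setMethod("show", "LineCloud", function(object) {
  cat(sprintf("LineCloud: %d inliers on y = x, %d noise points, seed %d\n",
              object@nInliers, object@nNoise, object@seed))
})
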