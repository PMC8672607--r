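#' Accessors
#'
#' Small accessor generics for the package classes: the intensity matrix in
#' analysis orientation (samples x features), identifiers, preprocessing
#' stage, and the fitted model components.
#'
#' @param x,object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname accessors
#' @export
setGeneric("projectionMatrix", function(x) standardGeneric("projectionMatrix"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("scalingParams", function(x) standardGeneric("scalingParams"))

#' @rdname accessors
setMethod("intensityMatrix", "MetaboTable", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname accessors
setMethod("sampleIds", "MetaboTable", function(x) colnames(x))

#' @rdname accessors
setMethod("featureIds", "MetaboTable", function(x) rownames(x))

#' @rdname accessors
setMethod("stage", "MetaboTable", function(x) x@stage)

#' @rdname accessors
setMethod("classNames", "ClassLabels", function(x) x@classNames)

#' @rdname accessors
setMethod("classNames", "PdcrModel", function(x) x@classNames)

#' @rdname accessors
setMethod("featureIds", "PdcrModel", function(x) x@featureIds)

#' @rdname accessors
setMethod("projectionMatrix", "PdcrModel", function(x) x@W)

#' @rdname accessors
setMethod("centroids", "PdcrModel", function(x) x@mu)

#' @rdname accessors
setMethod("scalingParams", "PdcrModel", function(x) x@scaling)

setMethod("show", "MetaboTable", function(object) {
  cat(sprintf("MetaboTable (%s): %d samples x %d features\n",
              object@stage, ncol(object), nrow(object)))
})

setMethod("show", "ClassLabels", function(object) {
  cat(sprintf("ClassLabels: %d samples, %d classes (%s)\n",
              length(object@assignment), length(object@classNames),
              paste(object@classNames, collapse = ", ")))
})

setMethod("show", "SolverConfig", function(object) {
  st <- if (object@autoSteps) "auto (0.99/||A||)"
        else sprintf("sigma=%g tau=%g", object@sigma, object@tau)
  cat(sprintf(
    "SolverConfig: loss=%s delta=%g rhoPenalty=%g eta=%g steps=%s maxIter=%d tol=%g\n",
    object@loss, object@delta, object@rhoPenalty, object@eta, st,
    object@maxIter, object@tol))
})

setMethod("show", "PdcrSolution", function(object) {
  cat(sprintf(
    "PdcrSolution: %d x %d W (%d nonzero), %d iterations, %sconverged\n",
    nrow(object@W), ncol(object@W), sum(object@W != 0),
    object@iterationsRun, if (object@converged) "" else "NOT "))
})

setMethod("show", "PdcrModel", function(object) {
  nsel <- sum(rowSums(abs(object@W)) > 0)
  cat(sprintf("PdcrModel: %d classes (%s)\n",
              length(object@classNames),
              paste(object@classNames, collapse = ", ")))
  cat(sprintf("  %d retained features, %d selected (nonzero weight)\n",
              length(object@featureIds), nsel))
  cat(sprintf("  loss=%s eta=%g, %d iterations, %sconverged\n",
              object@config@loss, object@config@eta, object@iterationsRun,
              if (object@converged) "" else "NOT "))
})

setMethod("show", "PdcrCVReport", function(object) {
  cat(sprintf(
    "PdcrCVReport: %d-fold CV, %d seed(s); mean accuracy %.4f, mean AUC %s\n",
    object@folds, length(object@seeds), object@meanAccuracy,
    if (is.na(object@meanAuc)) "NA" else sprintf("%.4f", object@meanAuc)))
})
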