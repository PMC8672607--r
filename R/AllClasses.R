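#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

.STAGES <- c("raw", "logged", "scaled")

#' MetaboTable: an intensity feature table
#'
#' Container for a sample-by-feature intensity matrix, stored in
#' Bioconductor orientation (features as rows, samples as columns) on top of
#' \linkS4class{SummarizedExperiment}. The \code{stage} slot tracks where the
#' table sits in the preprocessing pipeline: \code{"raw"} (nonnegative
#' intensities as measured), \code{"logged"} (after log transformation) or
#' \code{"scaled"} (after per-feature centering and unit-variance scaling).
#'
#' @slot stage character, one of \code{"raw"}, \code{"logged"},
#'   \code{"scaled"}.
#' @export
setClass("MetaboTable",
  contains = "SummarizedExperiment",
  slots = c(stage = "character")
)

setValidity("MetaboTable", function(object) {
  msg <- character()
  if (length(object@stage) != 1L || !object@stage %in% .STAGES)
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.STAGES, collapse = ", ")))
  v <- SummarizedExperiment::assay(object, "intensity")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicated sample identifiers")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicated feature identifiers")
  if (is.null(colnames(v)) || is.null(rownames(v)))
    msg <- c(msg, "sample and feature identifiers are required")
  if (identical(object@stage, "raw") && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "raw intensities must be nonnegative")
  if (identical(object@stage, "scaled") && any(!is.finite(v)))
    msg <- c(msg, "scaled values must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboTable
#'
#' @param values numeric matrix of intensities, samples in rows and features
#'   in columns (the orientation of a typical exported LC-MS feature table).
#' @param sampleIds,featureIds character vectors of unique identifiers;
#'   defaults are taken from the dimnames of \code{values}.
#' @param stage preprocessing stage, see \linkS4class{MetaboTable}.
#' @return A \linkS4class{MetaboTable}.
#' @examples
#' mt <- MetaboTable(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("f1", "f2", "f3"))))
#' dim(mt)
#' @export
MetaboTable <- function(values, sampleIds = rownames(values),
                        featureIds = colnames(values), stage = "raw") {
  values <- as.matrix(values)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(featureIds))
    featureIds <- sprintf("F%04d", seq_len(ncol(values)))
  a <- t(values)
  dimnames(a) <- list(as.character(featureIds), as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = a))
  new("MetaboTable", se, stage = stage)
}

#' ScalingParams: fitted preprocessing parameters
#'
#' Per-feature means and standard deviations learned on a training partition,
#' plus the pseudocount and log base of the preceding log transformation, so
#' that unseen samples can be transformed identically at prediction time.
#'
#' @slot means,scales numeric vectors, one entry per feature.
#' @slot pseudocount positive real added before taking logs.
#' @slot logBase base of the log transformation.
#' @export
setClass("ScalingParams", slots = c(
  means = "numeric", scales = "numeric",
  pseudocount = "numeric", logBase = "numeric"
))

setValidity("ScalingParams", function(object) {
  msg <- character()
  if (length(object@means) != length(object@scales))
    msg <- c(msg, "means and scales must have equal length")
  if (any(object@scales <= 0))
    msg <- c(msg, "scales must be strictly positive")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a nonnegative scalar")
  if (length(object@logBase) != 1L || object@logBase <= 0 ||
      object@logBase == 1)
    msg <- c(msg, "logBase must be positive and != 1")
  if (length(msg)) msg else TRUE
})

#' ClassLabels: encoded per-sample class assignment
#'
#' @slot classNames ordered (lexicographic) vector of the k >= 2 class names.
#' @slot assignment integer vector of class indices in 1..k, one per sample.
#' @slot onehot m x k binary indicator matrix, one 1 per row.
#' @export
setClass("ClassLabels", slots = c(
  classNames = "character", assignment = "integer", onehot = "matrix"
))

setValidity("ClassLabels", function(object) {
  msg <- character()
  k <- length(object@classNames)
  if (k < 2L) msg <- c(msg, "at least two classes are required")
  if (anyDuplicated(object@classNames))
    msg <- c(msg, "class names must be distinct")
  if (!all(object@assignment %in% seq_len(k)))
    msg <- c(msg, "assignment indices out of range")
  if (!all(tabulate(object@assignment, k) > 0L))
    msg <- c(msg, "every class must occur at least once")
  oh <- object@onehot
  if (nrow(oh) != length(object@assignment) || ncol(oh) != k) {
    msg <- c(msg, "onehot dimensions inconsistent with assignment")
  } else {
    ok <- all(rowSums(oh) == 1) &&
      all(oh[cbind(seq_len(nrow(oh)), object@assignment)] == 1)
    if (!ok) msg <- c(msg, "onehot rows must indicate exactly the assignment")
  }
  if (length(msg)) msg else TRUE
})

#' SolverConfig: parameters of the primal-dual solver
#'
#' @slot sigma,tau dual and primal step sizes; \code{NA} when
#'   \code{autoSteps} is on, in which case both are set to
#'   \code{0.99 / opnorm} so that \code{sigma * tau * opnorm^2 <= 1}.
#' @slot delta Huber knee: the loss is quadratic for residuals below
#'   \code{delta} and linear beyond.
#' @slot rhoPenalty weight of the centroid anchoring penalty
#'   \code{rho/2 * ||I_k - mu||_F^2}.
#' @slot eta radius of the entrywise l1 ball constraining the projection
#'   matrix W; smaller eta means fewer selected features.
#' @slot loss \code{"huber"} or \code{"squared_l2"}.
#' @slot maxIter,tol iteration cap and relative-change stopping tolerance.
#' @slot autoSteps derive sigma and tau from the operator norm.
#' @export
setClass("SolverConfig", slots = c(
  sigma = "numeric", tau = "numeric", delta = "numeric",
  rhoPenalty = "numeric", eta = "numeric", loss = "character",
  maxIter = "integer", tol = "numeric", autoSteps = "logical"
))

setValidity("SolverConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm, pos = TRUE, naOk = FALSE) {
    if (length(x) != 1L) return(sprintf("%s must be a scalar", nm))
    if (is.na(x)) {
      if (!naOk) return(sprintf("%s must not be NA", nm))
      return(NULL)
    }
    if (pos && x <= 0) return(sprintf("%s must be positive", nm))
    NULL
  }
  msg <- c(msg,
    chk1(object@sigma, "sigma", naOk = TRUE),
    chk1(object@tau, "tau", naOk = TRUE),
    chk1(object@delta, "delta"),
    chk1(object@rhoPenalty, "rhoPenalty"),
    chk1(object@tol, "tol"))
  if (length(object@eta) != 1L || is.na(object@eta) || object@eta < 0)
    msg <- c(msg, "eta must be a nonnegative scalar")
  if (!object@loss %in% c("huber", "squared_l2"))
    msg <- c(msg, "loss must be 'huber' or 'squared_l2'")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (!object@autoSteps && (is.na(object@sigma) || is.na(object@tau)))
    msg <- c(msg, "sigma and tau must be set when autoSteps = FALSE")
  if (length(msg)) msg else TRUE
})

#' Create a solver configuration
#'
#' Defaults follow the usual practice for this family of primal-dual
#' classifiers: the step sizes are derived from the operator norm
#' (\code{sigma = tau = 0.99 / ||A||}), the Huber knee \code{delta} and the
#' centroid penalty \code{rhoPenalty} are fixed, and only \code{eta} (the
#' sparsity budget) is meant to be tuned per dataset.
#'
#' @param sigma,tau step sizes; leave \code{NA} with \code{autoSteps = TRUE}.
#' @param delta Huber knee (default 0.3).
#' @param rhoPenalty centroid penalty weight (default 1).
#' @param eta l1-ball radius for W (default 1).
#' @param loss \code{"huber"} (robust, default) or \code{"squared_l2"}.
#' @param maxIter,tol stopping rule: at most \code{maxIter} iterations or
#'   relative iterate change below \code{tol}.
#' @param autoSteps derive steps from the estimated operator norm.
#' @return A \linkS4class{SolverConfig}.
#' @examples
#' solverConfig(eta = 2)
#' @export
solverConfig <- function(sigma = NA_real_, tau = NA_real_, delta = 0.3,
                         rhoPenalty = 1, eta = 1,
                         loss = c("huber", "squared_l2"),
                         maxIter = 2000L, tol = 1e-6, autoSteps = TRUE) {
  loss <- match.arg(loss)
  if (!is.na(sigma) || !is.na(tau)) autoSteps <- FALSE
  new("SolverConfig", sigma = as.numeric(sigma), tau = as.numeric(tau),
      delta = as.numeric(delta), rhoPenalty = as.numeric(rhoPenalty),
      eta = as.numeric(eta), loss = loss, maxIter = as.integer(maxIter),
      tol = as.numeric(tol), autoSteps = isTRUE(autoSteps))
}

#' PdcrSolution: output of the primal-dual solver
#'
#' @slot W d x k projection matrix (entrywise l1 norm <= eta).
#' @slot mu k x k centroid matrix, row j the centroid of class j.
#' @slot objectiveTrace objective value at every iteration.
#' @slot iterationsRun,converged stopping diagnostics.
#' @slot maxL1Norm largest entrywise l1 norm of W observed over all
#'   iterates (feasibility certificate).
#' @export
setClass("PdcrSolution", slots = c(
  W = "matrix", mu = "matrix", objectiveTrace = "numeric",
  iterationsRun = "integer", converged = "logical", maxL1Norm = "numeric"
))

#' PdcrModel: a fitted sparse primal-dual centroid classifier
#'
#' Holds everything needed to score unseen raw samples exactly as the
#' training samples were scored: the learned projection \code{W} and
#' centroids \code{mu}, the prevalence-filter feature selection, and the
#' fitted log/scaling parameters.
#'
#' @slot W d x k projection matrix over the retained features.
#' @slot mu k x k centroid matrix.
#' @slot classNames class names in the (lexicographic) label-encoding order.
#' @slot featureIds retained feature identifiers (rows of W).
#' @slot trainingFeatureIds all feature identifiers seen at fit time,
#'   before prevalence filtering.
#' @slot scaling fitted \linkS4class{ScalingParams}.
#' @slot config the \linkS4class{SolverConfig} used.
#' @slot minFraction prevalence-filter threshold used.
#' @slot iterationsRun,converged solver diagnostics.
#' @export
setClass("PdcrModel", slots = c(
  W = "matrix", mu = "matrix", classNames = "character",
  featureIds = "character", trainingFeatureIds = "character",
  scaling = "ScalingParams", config = "SolverConfig",
  minFraction = "numeric", iterationsRun = "integer", converged = "logical"
))

setValidity("PdcrModel", function(object) {
  msg <- character()
  k <- length(object@classNames)
  if (ncol(object@W) != k || nrow(object@mu) != k || ncol(object@mu) != k)
    msg <- c(msg, "W columns and mu dimensions must equal the class count")
  if (nrow(object@W) != length(object@featureIds))
    msg <- c(msg, "W rows must match featureIds")
  if (sum(abs(object@W)) > object@config@eta + 1e-9)
    msg <- c(msg, "W violates the l1-ball constraint")
  if (length(msg)) msg else TRUE
})

#' PdcrCVReport: stratified cross-validation results
#'
#' @slot perFoldAccuracy seeds x folds matrix of held-out accuracies.
#' @slot meanAccuracy,meanAuc grand means over all seeds and folds.
#' @slot perFoldTopFeatures nested list (per seed, per fold) of the
#'   top-ranked features in each training-fold model.
#' @slot predictions pooled held-out predictions (seed, fold, sampleId,
#'   truth, predictedClass, csp).
#' @slot folds,seeds,config the protocol that produced the report.
#' @export
setClass("PdcrCVReport", slots = c(
  perFoldAccuracy = "matrix", meanAccuracy = "numeric", meanAuc = "numeric",
  perFoldTopFeatures = "list", predictions = "data.frame",
  folds = "integer", seeds = "integer", config = "SolverConfig"
))
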