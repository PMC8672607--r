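#' Fit the sparse primal-dual centroid classifier
#'
#' Runs the full training pipeline on a raw intensity table: prevalence
#' filtering, log transformation, autoscaling (all fitted on these training
#' samples only), then the primal-dual solver that jointly learns the sparse
#' projection W and the class centroids mu. The returned model stores every
#' fitted parameter so unseen raw samples are transformed identically at
#' prediction time.
#'
#' @param x a raw-stage \linkS4class{MetaboTable}.
#' @param labels a \linkS4class{ClassLabels} or a vector of per-sample
#'   labels aligned with the samples of \code{x}.
#' @param config a \linkS4class{SolverConfig}; \code{eta} is the one
#'   parameter worth tuning per dataset (it sets the feature budget).
#' @param minFraction prevalence-filter threshold (default 0.1).
#' @param pseudocount,logBase log-transform parameters.
#' @return A \linkS4class{PdcrModel}.
#' @examples
#' sim <- simulateMetabolomics(m = 24, d = 40, s = 3, seed = 7)
#' fit <- pdcrFit(sim$table, sim$truth$labels, solverConfig(eta = 2))
#' fit
#' @export
pdcrFit <- function(x, labels, config = solverConfig(), minFraction = 0.1,
                    pseudocount = 1, logBase = 10) {
  stopifnot(is(x, "MetaboTable"))
  if (!is(labels, "ClassLabels")) labels <- encodeLabels(labels)
  m <- ncol(x)
  if (length(labels@assignment) != m)
    stop(sprintf("table has %d samples but labels describe %d",
                 m, length(labels@assignment)))
  if (config@eta == 0)
    warning("eta = 0 forces W = 0: no features will be selected")
  allIds <- featureIds(x)
  filt <- prevalenceFilter(x, minFraction)
  logged <- logTransform(filt, pseudocount = pseudocount, base = logBase)
  scaling <- fitScaling(logged, pseudocount = pseudocount, logBase = logBase)
  scaled <- applyScaling(logged, scaling)
  sol <- pdSolve(intensityMatrix(scaled), labels@onehot, config)
  W <- sol@W; mu <- sol@mu
  dimnames(W) <- list(featureIds(filt), labels@classNames)
  dimnames(mu) <- list(labels@classNames, labels@classNames)
  new("PdcrModel", W = W, mu = mu, classNames = labels@classNames,
      featureIds = featureIds(filt), trainingFeatureIds = allIds,
      scaling = scaling, config = config, minFraction = minFraction,
      iterationsRun = sol@iterationsRun, converged = sol@converged)
}

# raw samples x features matrix -> scaled matrix over the model's
# retained features, replaying the stored transforms
.transformForModel <- function(model, values, featureNames) {
  kept <- model@featureIds
  if (!setequal(featureNames, model@trainingFeatureIds) &&
      !setequal(featureNames, kept)) {
    extra <- setdiff(featureNames, model@trainingFeatureIds)
    missing <- setdiff(kept, featureNames)
    stop("feature mismatch with the fitted model",
         if (length(missing)) paste0("; missing: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..."),
         if (length(extra)) paste0("; unknown: ",
           paste(utils::head(extra, 5), collapse = ", "),
           if (length(extra) > 5) ", ..."))
  }
  v <- values[, match(kept, featureNames), drop = FALSE]
  if (any(v < 0)) stop("raw intensities must be nonnegative")
  sc <- model@scaling
  v <- log(v + sc@pseudocount, base = sc@logBase)
  sweep(sweep(v, 2L, sc@means, "-"), 2L, sc@scales, "/")
}

#' l1 distances of a scaled sample to the class centroids
#'
#' For a sample x already on the scaled stage, computes
#' \code{d_j = sum_l |mu_j[l] - (x W)[l]|} for every class j: the distances
#' that drive both the nearest-centroid decision and the confidence score.
#'
#' @param model a fitted \linkS4class{PdcrModel}.
#' @param x numeric vector of length d (the model's retained features, in
#'   model order), already transformed with the model's scaling.
#' @return Named length-k vector of l1 distances.
#' @export
distancesToCentroids <- function(model, x) {
  stopifnot(is(model, "PdcrModel"))
  x <- as.numeric(x)
  if (length(x) != nrow(model@W))
    stop(sprintf("sample has %d features but model expects %d",
                 length(x), nrow(model@W)))
  p <- drop(crossprod(model@W, x))
  d <- rowSums(abs(sweep(model@mu, 2L, p, "-")))
  names(d) <- model@classNames
  d
}

# rows of P (m x k projections) vs centroid rows of mu -> m x k distances
.centroidDistances <- function(P, mu) {
  k <- nrow(mu)
  D <- matrix(0, nrow(P), k)
  for (j in seq_len(k))
    D[, j] <- rowSums(abs(sweep(P, 2L, mu[j, ], "-")))
  D
}

#' Binary confidence score for the prediction (CSP)
#'
#' \code{(d1 - d2) / (d1 + d2)}, ranging over \code{[-1, 1]}: negative means
#' closer to centroid 1, positive closer to centroid 2, and magnitude near 1
#' means high confidence. Degenerate geometry (both distances zero) yields 0
#' with a warning.
#'
#' @param d1,d2 nonnegative l1 distances to the two centroids (vectorized).
#' @return CSP values in \code{[-1, 1]}.
#' @examples
#' cspBinary(3, 1)  # 0.5
#' @export
cspBinary <- function(d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) stop("distances must be nonnegative")
  tot <- d1 + d2
  deg <- tot == 0
  if (any(deg)) {
    warning("degenerate geometry: both centroid distances are zero")
    tot[deg] <- 1
  }
  out <- (d1 - d2) / tot
  out[deg] <- 0
  out
}

#' Multi-class confidence score
#'
#' \code{1 - k * min(d) / sum(d)}, ranging over \code{[0, 1]}; 0 when the
#' sample is equidistant from all centroids, 1 when it sits on one centroid.
#' For k = 2 this equals the absolute value of \code{\link{cspBinary}}.
#'
#' @param d length-k vector of nonnegative distances.
#' @return CSP value in \code{[0, 1]}.
#' @export
cspMulticlass <- function(d) {
  d <- as.numeric(d)
  if (any(d < 0)) stop("distances must be nonnegative")
  if (sum(d) == 0) {
    warning("degenerate geometry: all centroid distances are zero")
    return(1)
  }
  1 - length(d) * min(d) / sum(d)
}

#' Predict classes, distances and confidence for raw samples
#'
#' Applies the model's stored transforms (prevalence selection, log,
#' scaling), projects with W, computes l1 distances to the centroids,
#' assigns each sample to the nearest centroid (ties to the lowest class
#' index), and attaches the confidence score: signed binary CSP when k = 2,
#' the multi-class CSP otherwise. With \code{epsilon > 0} low-confidence
#' calls are rejected (\code{finalLabel = "rejected"}); the boundary
#' \code{|csp| = epsilon} is classified, not rejected.
#'
#' @param object a fitted \linkS4class{PdcrModel}.
#' @param newdata a raw-stage \linkS4class{MetaboTable} (or a samples x
#'   features numeric matrix with feature column names) whose features match
#'   the model's training features (any order; unknown or missing features
#'   are an error, never silently dropped).
#' @param epsilon rejection threshold in \code{[0, 1]} (default 0: nothing
#'   rejected).
#' @param ... ignored.
#' @return A data.frame with columns \code{sampleId}, \code{d_1..d_k},
#'   \code{predictedClass}, \code{csp}, \code{rejected}, \code{finalLabel}.
#' @export
setMethod("predict", "PdcrModel", function(object, newdata, epsilon = 0, ...) {
  if (is(newdata, "MetaboTable")) {
    if (stage(newdata) != "raw")
      stop("predict expects a raw-stage table")
    v <- intensityMatrix(newdata)
    ids <- sampleIds(newdata)
  } else {
    v <- as.matrix(newdata)
    ids <- rownames(v)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(v)))
    if (is.null(colnames(v))) stop("newdata must carry feature names")
  }
  Xs <- .transformForModel(object, v, colnames(v))
  P <- Xs %*% object@W
  D <- .centroidDistances(P, object@mu)
  k <- length(object@classNames)
  pred <- max.col(-D, ties.method = "first")
  csp <- if (k == 2L) cspBinary(D[, 1L], D[, 2L])
         else apply(D, 1L, cspMulticlass)
  out <- data.frame(sampleId = ids, D,
                    predictedClass = object@classNames[pred],
                    csp = csp, stringsAsFactors = FALSE)
  names(out)[1L + seq_len(k)] <- paste0("d_", seq_len(k))
  predictWithRejection(out, epsilon)
})

#' Apply (or re-apply) the rejection rule to predictions
#'
#' Binary rule, kept with strict inequalities: predict class 1 when
#' \code{csp < -epsilon}, reject when \code{-epsilon < csp < epsilon},
#' predict class 2 when \code{csp > epsilon}; the boundary
#' \code{|csp| = epsilon} keeps the nearest-centroid call. With more than
#' two classes a sample is rejected when its (nonnegative) multi-class CSP
#' is below \code{epsilon}. Raising \code{epsilon} can only grow the
#' rejected set.
#'
#' @param predictions a prediction data.frame from
#'   \code{\link[=predict,PdcrModel-method]{predict}}.
#' @param epsilon rejection threshold in \code{[0, 1]}.
#' @return The data.frame with updated \code{rejected} and
#'   \code{finalLabel} columns.
#' @export
predictWithRejection <- function(predictions, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon > 1)
    stop("epsilon must be a single value in [0, 1]")
  predictions$rejected <- abs(predictions$csp) < epsilon
  predictions$finalLabel <- ifelse(predictions$rejected, "rejected",
                                   predictions$predictedClass)
  predictions
}

#' Rank features by their weight in the model
#'
#' The importance of feature f is \code{sum_j |W[f, j]|}: the direct
#' contribution of that feature to the learned projection. Features are
#' sorted by decreasing score, ties broken by feature index; zero-score
#' features are reported as unselected.
#'
#' @param model a fitted \linkS4class{PdcrModel}.
#' @return A data.frame with columns \code{featureId}, \code{score},
#'   \code{selected}, sorted by decreasing score.
#' @export
featureRanking <- function(model) {
  stopifnot(is(model, "PdcrModel"))
  score <- rowSums(abs(model@W))
  ord <- order(-score, seq_along(score))
  out <- data.frame(featureId = model@featureIds[ord], score = score[ord],
                    selected = score[ord] > 0, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!any(out$selected)) message("no features selected (all weights zero)")
  out
}
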