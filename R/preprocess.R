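#' Prevalence filter
#'
#' Removes features detected in too few samples. A feature counts as
#' detected in a sample when its raw intensity is strictly positive; the
#' feature is kept when the detected fraction is at least
#' \code{minFraction}. The common practice for LC-MS tables is to drop
#' features seen in fewer than 10\% of samples, hence the default.
#'
#' @param x a raw-stage \linkS4class{MetaboTable}.
#' @param minFraction minimum detected fraction in \code{[0, 1]}.
#' @return The filtered \linkS4class{MetaboTable}; the integer indices of
#'   the kept features (relative to the input) are stored in
#'   \code{metadata(x)$keptFeatures}.
#' @examples
#' mt <- MetaboTable(matrix(c(0, 0, 1, 2), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("f1", "f2"))))
#' featureIds(prevalenceFilter(mt, 0.5))
#' @export
prevalenceFilter <- function(x, minFraction = 0.1) {
  stopifnot(is(x, "MetaboTable"))
  if (stage(x) != "raw")
    stop("prevalenceFilter expects a raw-stage table, got stage '",
         stage(x), "'")
  if (!is.numeric(minFraction) || length(minFraction) != 1L ||
      minFraction < 0 || minFraction > 1)
    stop("minFraction must be a single value in [0, 1]")
  a <- SummarizedExperiment::assay(x, "intensity")
  frac <- rowMeans(a > 0)
  keep <- unname(which(frac >= minFraction))
  if (length(keep) == 0L)
    stop("prevalence filter removed all features (empty table)")
  out <- x[keep, ]
  S4Vectors::metadata(out)$keptFeatures <- keep
  out
}

#' Log transformation
#'
#' Applies \code{log_base(x + pseudocount)} entrywise. Log transformation
#' reduces heteroscedasticity of intensity data and turns multiplicative
#' noise into additive noise; the pseudocount guards the zeros produced by
#' detection dropout.
#'
#' @param x a raw-stage \linkS4class{MetaboTable} with nonnegative values.
#' @param pseudocount nonnegative offset; must be positive unless every
#'   value is strictly positive.
#' @param base log base (default 10).
#' @return The transformed table at stage \code{"logged"}.
#' @export
logTransform <- function(x, pseudocount = 1, base = 10) {
  stopifnot(is(x, "MetaboTable"))
  if (stage(x) != "raw")
    stop("logTransform expects a raw-stage table, got stage '", stage(x), "'")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (base <= 0 || base == 1) stop("log base must be positive and != 1")
  a <- SummarizedExperiment::assay(x, "intensity")
  if (any(a < 0)) stop("raw intensities must be nonnegative")
  if (pseudocount == 0 && any(a == 0)) {
    idx <- which(a == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "zero intensity with pseudocount 0 (feature '%s', sample '%s')",
      rownames(a)[idx[1L]], colnames(a)[idx[2L]]))
  }
  SummarizedExperiment::assay(x, "intensity") <-
    log(a + pseudocount, base = base)
  x@stage <- "logged"
  validObject(x)
  x
}

#' Fit autoscaling parameters
#'
#' Learns per-feature means and sample (n-1) standard deviations on a logged
#' table. Zero-variance features get a fallback scale of 1 (with a warning)
#' so that constant features pass through centered at 0 instead of producing
#' division-by-zero artifacts. Always fit on the training partition only.
#'
#' @param x a logged-stage \linkS4class{MetaboTable} with at least 2 samples.
#' @param pseudocount,logBase recorded alongside so a model can replay the
#'   full raw-to-scaled transform on unseen samples.
#' @return A \linkS4class{ScalingParams}.
#' @export
fitScaling <- function(x, pseudocount = 1, logBase = 10) {
  stopifnot(is(x, "MetaboTable"))
  if (stage(x) != "logged")
    stop("fitScaling expects a logged-stage table, got stage '",
         stage(x), "'")
  v <- intensityMatrix(x)
  if (nrow(v) < 2L)
    stop("at least 2 samples are needed to estimate standard deviations")
  means <- colMeans(v)
  scales <- apply(v, 2L, stats::sd)
  zv <- scales == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance feature(s); scale set to 1")
    scales[zv] <- 1
  }
  names(means) <- names(scales) <- featureIds(x)
  new("ScalingParams", means = means, scales = scales,
      pseudocount = as.numeric(pseudocount), logBase = as.numeric(logBase))
}

#' Apply autoscaling
#'
#' Centers and scales each feature with previously fitted parameters:
#' \code{(value - mean) / scale}.
#'
#' @param x a logged-stage \linkS4class{MetaboTable}.
#' @param params a \linkS4class{ScalingParams} with one entry per feature
#'   of \code{x}.
#' @return The table at stage \code{"scaled"}.
#' @export
applyScaling <- function(x, params) {
  stopifnot(is(x, "MetaboTable"), is(params, "ScalingParams"))
  if (stage(x) != "logged")
    stop("applyScaling expects a logged-stage table, got stage '",
         stage(x), "'")
  d <- nrow(x)
  if (length(params@means) != d)
    stop(sprintf("scaling parameters cover %d features but table has %d",
                 length(params@means), d))
  a <- SummarizedExperiment::assay(x, "intensity")
  SummarizedExperiment::assay(x, "intensity") <-
    (a - params@means) / params@scales
  x@stage <- "scaled"
  validObject(x)
  x
}

#' Encode class labels
#'
#' Turns a character/factor vector of per-sample labels into a
#' \linkS4class{ClassLabels} object: class names sorted lexicographically
#' (so label order is deterministic), integer assignments and the one-hot
#' indicator matrix Y used by the solver.
#'
#' @param labels vector of length m with at least two distinct values and
#'   no missing entries.
#' @return A \linkS4class{ClassLabels}.
#' @examples
#' encodeLabels(c("ctl", "case", "ctl"))
#' @export
encodeLabels <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("missing labels are not allowed")
  cls <- sort(unique(labels), method = "radix")
  if (length(cls) < 2L)
    stop("at least two distinct classes are required, got ", length(cls))
  assignment <- match(labels, cls)
  onehot <- matrix(0, length(labels), length(cls),
                   dimnames = list(NULL, cls))
  onehot[cbind(seq_along(labels), assignment)] <- 1
  new("ClassLabels", classNames = cls, assignment = as.integer(assignment),
      onehot = onehot)
}

#' Decode class labels
#'
#' @param labels a \linkS4class{ClassLabels}.
#' @return The character vector of per-sample class names.
#' @export
decodeLabels <- function(labels) {
  stopifnot(is(labels, "ClassLabels"))
  labels@classNames[labels@assignment]
}
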