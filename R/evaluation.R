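#' Classification accuracy
#'
#' Fraction of exact matches between predicted and true labels. Rejected
#' samples must be excluded before calling (accuracy is defined on
#' classified samples).
#'
#' @param predicted,truth equal-length vectors of class labels.
#' @return Accuracy in \code{[0, 1]}.
#' @export
accuracyScore <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(predicted), length(truth)))
  if (length(predicted) == 0L) stop("empty input")
  mean(as.character(predicted) == as.character(truth))
}

#' Area under the ROC curve from continuous scores
#'
#' Mann-Whitney AUC: the probability that a random positive sample scores
#' higher than a random negative one, with ties counted 1/2. Computed from
#' mid-ranks, equivalent to exhaustive pair counting.
#'
#' @param scores numeric vector (higher = more positive-like).
#' @param truth binary vector (logical, 0/1, or two-level factor/character;
#'   the lexicographically larger level is the positive class).
#' @return AUC in \code{[0, 1]}.
#' @examples
#' aucFromScores(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
aucFromScores <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  if (is.logical(truth)) truth <- as.integer(truth)
  if (!is.numeric(truth)) {
    lev <- sort(unique(as.character(truth)), method = "radix")
    if (length(lev) != 2L)
      stop("truth must contain exactly two classes, got ", length(lev))
    truth <- as.integer(as.character(truth) == lev[2L])
  }
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation
#'
#' The evaluation protocol: for each seed, samples are shuffled within each
#' class and dealt into \code{folds} folds (stratified; fold sizes differ by
#' at most one). Each fold is held out in turn while the model - including
#' prevalence filter and scaling, which are refit on the training folds only
#' so no test information leaks - is fitted on the remainder and evaluated
#' on the held-out fold. Accuracy is aggregated per fold; for binary tasks
#' the AUC of the signed confidence score is pooled per seed.
#'
#' @param x a raw-stage \linkS4class{MetaboTable}.
#' @param labels a \linkS4class{ClassLabels} or label vector.
#' @param folds number of folds (default 4).
#' @param seeds integer vector of shuffle seeds (default \code{0:2}).
#' @param config a \linkS4class{SolverConfig}.
#' @param minFraction,pseudocount,logBase preprocessing options passed to
#'   \code{\link{pdcrFit}}.
#' @param topFeatures how many top-ranked features to record per fold.
#' @return A \linkS4class{PdcrCVReport}.
#' @export
pdcrCrossValidate <- function(x, labels, folds = 4L, seeds = 0:2,
                              config = solverConfig(), minFraction = 0.1,
                              pseudocount = 1, logBase = 10,
                              topFeatures = 10L) {
  stopifnot(is(x, "MetaboTable"))
  if (!is(labels, "ClassLabels")) labels <- encodeLabels(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  m <- ncol(x)
  if (length(labels@assignment) != m)
    stop("labels do not match the table's samples")
  sizes <- tabulate(labels@assignment, length(labels@classNames))
  if (any(sizes < folds))
    stop(sprintf(
      "smallest class has %d samples; cannot stratify into %d folds",
      min(sizes), folds))
  truthAll <- decodeLabels(labels)
  k <- length(labels@classNames)
  acc <- matrix(NA_real_, length(seeds), folds,
                dimnames = list(paste0("seed", seeds), NULL))
  aucs <- numeric(0)
  topFeats <- vector("list", length(seeds))
  predRows <- list()
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    ord <- unlist(lapply(seq_len(k), function(cl) {
      idx <- which(labels@assignment == cl)
      idx[sample.int(length(idx))]
    }))
    foldOf <- integer(m)
    foldOf[ord] <- rep(seq_len(folds), length.out = m)
    topFeats[[si]] <- vector("list", folds)
    seedPred <- list()
    for (f in seq_len(folds)) {
      test <- which(foldOf == f)
      train <- which(foldOf != f)
      fit <- pdcrFit(x[, train], truthAll[train], config = config,
                     minFraction = minFraction, pseudocount = pseudocount,
                     logBase = logBase)
      pr <- predict(fit, x[, test])
      acc[si, f] <- accuracyScore(pr$predictedClass, truthAll[test])
      rk <- featureRanking(fit)
      topFeats[[si]][[f]] <- utils::head(rk$featureId[rk$selected],
                                         topFeatures)
      seedPred[[f]] <- data.frame(seed = seeds[si], fold = f,
                                  sampleId = pr$sampleId,
                                  truth = truthAll[test],
                                  predictedClass = pr$predictedClass,
                                  csp = pr$csp, stringsAsFactors = FALSE)
    }
    seedDf <- do.call(rbind, seedPred)
    predRows[[si]] <- seedDf
    if (k == 2L)
      aucs <- c(aucs, aucFromScores(seedDf$csp, seedDf$truth))
  }
  new("PdcrCVReport", perFoldAccuracy = acc, meanAccuracy = mean(acc),
      meanAuc = if (k == 2L) mean(aucs) else NA_real_,
      perFoldTopFeatures = topFeats,
      predictions = do.call(rbind, predRows), folds = folds,
      seeds = as.integer(seeds), config = config)
}

#' FDR and rejection-rate curves over the confidence threshold
#'
#' For each threshold \code{epsilon} in the grid, applies the rejection rule
#' and reports: \code{fdr}, the number of misclassified non-rejected samples
#' divided by the \emph{total} number of samples (the misclassification-load
#' convention used with this classifier); \code{fdrConditional}, the same
#' count divided by the number of accepted samples (the conventional rate);
#' and \code{rrs}, rejected samples over total samples. On any grid the FDR
#' is non-increasing and the RRS non-decreasing in \code{epsilon}.
#'
#' @param predictions a binary-task prediction data.frame (needs columns
#'   \code{csp} and \code{predictedClass}).
#' @param truth true class labels aligned with the predictions.
#' @param epsilons increasing grid in \code{[0, 1]}.
#' @return A data.frame with columns \code{epsilon}, \code{fdr},
#'   \code{fdrConditional}, \code{rrs}.
#' @export
rejectionCurve <- function(predictions, truth,
                           epsilons = seq(0, 1, by = 0.01)) {
  if (nrow(predictions) == 0L) stop("empty predictions")
  if (length(truth) != nrow(predictions))
    stop("truth must align with predictions")
  if (any(epsilons < 0 | epsilons > 1)) stop("epsilons must lie in [0, 1]")
  wrong <- predictions$predictedClass != as.character(truth)
  n <- nrow(predictions)
  rows <- lapply(epsilons, function(e) {
    rej <- abs(predictions$csp) < e
    err <- sum(wrong & !rej)
    acc <- sum(!rej)
    data.frame(epsilon = e, fdr = err / n,
               fdrConditional = if (acc > 0) err / acc else 0,
               rrs = sum(rej) / n)
  })
  do.call(rbind, rows)
}

#' Per-class histogram of confidence scores
#'
#' Bins the signed CSP values over \code{[-1, 1]} separately for each true
#' class; with a well-behaved classifier the two classes pile up near the
#' opposite ends.
#'
#' @param predictions a prediction data.frame with a \code{csp} column.
#' @param truth true class labels.
#' @param breaks bin edges covering \code{[-1, 1]} (default 20 equal bins).
#' @return A data.frame with columns \code{binLow}, \code{binHigh},
#'   \code{class}, \code{count}; counts sum to the number of samples.
#' @export
cspHistogram <- function(predictions, truth,
                         breaks = seq(-1, 1, length.out = 21L)) {
  truth <- as.character(truth)
  if (length(truth) != nrow(predictions))
    stop("truth must align with predictions")
  bins <- cut(predictions$csp, breaks = breaks, include.lowest = TRUE)
  tab <- table(bins, truth)
  out <- expand.grid(bin = seq_len(length(breaks) - 1L),
                     class = colnames(tab), stringsAsFactors = FALSE)
  data.frame(binLow = breaks[out$bin], binHigh = breaks[out$bin + 1L],
             class = out$class,
             count = as.integer(tab[cbind(out$bin,
                                          match(out$class, colnames(tab)))]))
}
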