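#' Read a feature table from CSV
#'
#' Expected layout: header row of feature names, first column the sample
#' identifier, remaining cells numeric intensities
#' (\code{orientation = "samples-rows"}). Exported tables with features in
#' rows and samples in columns are accepted with
#' \code{orientation = "features-rows"}. Duplicate identifiers and
#' non-numeric cells are rejected with the offending coordinates.
#'
#' @param path CSV file path.
#' @param orientation \code{"samples-rows"} (default) or
#'   \code{"features-rows"}.
#' @return A raw-stage \linkS4class{MetaboTable}.
#' @export
readFeatureTable <- function(path,
                             orientation = c("samples-rows",
                                             "features-rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs an id column plus data")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated identifier(s) in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hdr <- colnames(df)[-1L]
  if (anyDuplicated(hdr))
    stop("duplicated column name(s): ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  for (j in bad) {
    conv <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(conv) && !anyNA(vals[[j]]))
      stop(sprintf("non-numeric cell in column '%s', row %d ('%s')",
                   hdr[j], which(is.na(conv))[1L],
                   vals[[j]][which(is.na(conv))[1L]]))
    vals[[j]] <- conv
  }
  mx <- as.matrix(vals)
  if (anyNA(mx)) {
    idx <- which(is.na(mx), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column '%s'",
                 idx[1L], hdr[idx[2L]]))
  }
  rownames(mx) <- ids
  if (orientation == "features-rows") mx <- t(mx)
  MetaboTable(mx, stage = "raw")
}

#' Write a feature table to CSV
#'
#' Inverse of \code{\link{readFeatureTable}} for the
#' \code{"samples-rows"} layout.
#'
#' @param table a \linkS4class{MetaboTable}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  v <- intensityMatrix(table)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-sample labels from a two-column CSV
#'
#' The file must have columns \code{sample_id} and \code{label} (header
#' names are free; the first two columns are used). Every requested sample
#' id must be present (the join is total).
#'
#' @param path CSV file path.
#' @param sampleIds sample identifiers to align the labels with, in order.
#' @return Character vector of labels in the order of \code{sampleIds}.
#' @export
readSampleLabels <- function(path, sampleIds) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns (sample_id,label)")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated sample id(s) in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hit <- match(sampleIds, ids)
  if (anyNA(hit))
    stop("label file is missing sample(s): ",
         paste(utils::head(sampleIds[is.na(hit)], 5), collapse = ", "))
  as.character(df[[2L]])[hit]
}

#' Serialize a fitted model to JSON
#'
#' The model is written as a human-inspectable JSON document (the feature
#' weights in W are a headline output of the method) at full floating-point
#' precision, so \code{\link{readPdcrModel}} round-trips to bit-identical
#' predictions.
#'
#' @param model a \linkS4class{PdcrModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePdcrModel <- function(model, path) {
  stopifnot(is(model, "PdcrModel"))
  cfg <- model@config
  doc <- list(
    format_version = 1L,
    class_names = model@classNames,
    feature_ids = model@featureIds,
    training_feature_ids = model@trainingFeatureIds,
    W = asplit(unname(model@W), 1L),        # row-major
    mu = asplit(unname(model@mu), 1L),
    scaling = list(means = unname(model@scaling@means),
                   scales = unname(model@scaling@scales),
                   pseudocount = model@scaling@pseudocount,
                   log_base = model@scaling@logBase),
    config_used = list(auto_steps = cfg@autoSteps,
                       sigma = if (is.na(cfg@sigma)) "auto" else cfg@sigma,
                       tau = if (is.na(cfg@tau)) "auto" else cfg@tau,
                       delta = cfg@delta,
                       rho_penalty = cfg@rhoPenalty, eta = cfg@eta,
                       loss = cfg@loss, max_iter = cfg@maxIter,
                       tol = cfg@tol),
    min_fraction = model@minFraction,
    iterations_run = model@iterationsRun,
    converged = model@converged
  )
  # I(17) significant digits: doubles survive the text round-trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path a file written by \code{\link{writePdcrModel}}.
#' @return The reconstructed \linkS4class{PdcrModel}.
#' @export
readPdcrModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) || doc$format_version != 1L)
    stop("unsupported model format version")
  cfg <- doc$config_used
  asStep <- function(x) {
    if (is.null(x) || identical(x, "auto")) NA_real_ else as.numeric(x)
  }
  config <- new("SolverConfig",
    sigma = asStep(cfg$sigma), tau = asStep(cfg$tau),
    delta = as.numeric(cfg$delta), rhoPenalty = as.numeric(cfg$rho_penalty),
    eta = as.numeric(cfg$eta), loss = cfg$loss,
    maxIter = as.integer(cfg$max_iter), tol = as.numeric(cfg$tol),
    autoSteps = isTRUE(cfg$auto_steps))
  W <- matrix(unlist(doc$W, use.names = FALSE),
              nrow = length(doc$feature_ids), byrow = is.list(doc$W))
  if (is.matrix(doc$W)) W <- doc$W
  mu <- if (is.matrix(doc$mu)) doc$mu else
    matrix(unlist(doc$mu, use.names = FALSE),
           nrow = length(doc$class_names), byrow = TRUE)
  scaling <- new("ScalingParams",
                 means = stats::setNames(doc$scaling$means, doc$feature_ids),
                 scales = stats::setNames(doc$scaling$scales,
                                          doc$feature_ids),
                 pseudocount = doc$scaling$pseudocount,
                 logBase = doc$scaling$log_base)
  dimnames(W) <- list(doc$feature_ids, doc$class_names)
  dimnames(mu) <- list(doc$class_names, doc$class_names)
  new("PdcrModel", W = W, mu = mu, classNames = doc$class_names,
      featureIds = doc$feature_ids,
      trainingFeatureIds = doc$training_feature_ids, scaling = scaling,
      config = config, minFraction = doc$min_fraction,
      iterationsRun = as.integer(doc$iterations_run),
      converged = doc$converged)
}

#' Write predictions to CSV
#'
#' Columns: \code{sample_id}, \code{d_1..d_k}, \code{predicted_class},
#' \code{csp}, \code{final_label}.
#'
#' @param predictions a prediction data.frame from
#'   \code{\link[=predict,PdcrModel-method]{predict}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(predictions, path) {
  dcols <- grep("^d_", names(predictions), value = TRUE)
  out <- cbind(data.frame(sample_id = predictions$sampleId),
               predictions[dcols],
               data.frame(predicted_class = predictions$predictedClass,
                          csp = predictions$csp,
                          final_label = predictions$finalLabel))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
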