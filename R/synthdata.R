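#' Simulate a two-class LC-MS-like feature table with known ground truth
#'
#' Generates the structure that makes metabolomics tables hard: lognormal
#' intensities, a small set of discriminative metabolites each observed as a
#' block of highly correlated adduct/isotopologue features, detection
#' dropout producing exact zeros, and (optionally) outlier samples with
#' inflated noise.
#'
#' On the log10 scale: each background feature has a mean drawn uniformly
#' from \code{baseLog10MeanRange}, identical in both classes, plus
#' N(0, \code{featureSdLog10}) per-sample noise. Each of the \code{s}
#' informative base metabolites gets \code{log2FoldChange * log10(2)} added
#' to its mean in class 2; its \code{adductsPerBase} feature columns share
#' the base's per-sample signal, each with a fixed per-adduct offset and
#' N(0, \code{adductJitterSd}) measurement jitter, so within-block Pearson
#' correlation is high (about 0.97 at the defaults). Intensities are
#' \code{10^log10}; every entry is then zeroed with probability
#' \code{dropoutProb}. A fraction \code{outlierSampleFrac} of samples has
#' all per-sample noise standard deviations multiplied by
#' \code{outlierScale}, emulating degraded runs. Output is deterministic
#' given \code{seed}; feature columns are placed in random order.
#'
#' @param m samples, split into two balanced classes (default 100).
#' @param d features (default 1000).
#' @param s informative base metabolites (default 10).
#' @param adductsPerBase correlated features per base metabolite (default 3).
#' @param log2FoldChange class-2 effect on each base metabolite, in log2
#'   units (default 1.6, i.e. a ~3-fold intensity change).
#' @param baseLog10MeanRange range of feature log10 means (default [3, 6]).
#' @param featureSdLog10 per-sample biological noise sd, log10 scale
#'   (default 0.3).
#' @param adductJitterSd within-block measurement jitter sd (default 0.05).
#' @param dropoutProb probability an entry is zeroed (default 0.1).
#' @param outlierSampleFrac fraction of outlier samples (default 0).
#' @param outlierScale noise-sd multiplier for outlier samples (default 5).
#' @param seed integer seed.
#' @return A list with \code{table} (a raw \linkS4class{MetaboTable}) and
#'   \code{truth}: the \linkS4class{ClassLabels}, the
#'   \code{informativeFeatureIds} (all adduct copies), a \code{blockMap}
#'   from base metabolite to member features, the \code{outlierSamples},
#'   and an echo of the generator settings.
#' @examples
#' sim <- simulateMetabolomics(m = 20, d = 50, s = 3, seed = 1)
#' sim$table
#' length(sim$truth$informativeFeatureIds)
#' @export
simulateMetabolomics <- function(m = 100L, d = 1000L, s = 10L,
                                 adductsPerBase = 3L, log2FoldChange = 1.6,
                                 baseLog10MeanRange = c(3, 6),
                                 featureSdLog10 = 0.3, adductJitterSd = 0.05,
                                 dropoutProb = 0.1, outlierSampleFrac = 0,
                                 outlierScale = 5, seed = 1L) {
  if (s * adductsPerBase > d)
    stop("s * adductsPerBase must not exceed d")
  if (m < 4L) stop("need at least 4 samples")
  if (dropoutProb < 0 || dropoutProb >= 1)
    stop("dropoutProb must lie in [0, 1)")
  if (outlierSampleFrac < 0 || outlierSampleFrac >= 1)
    stop("outlierSampleFrac must lie in [0, 1)")
  if (featureSdLog10 <= 0 || adductJitterSd < 0 || outlierScale <= 0)
    stop("noise parameters out of domain")
  set.seed(seed)
  nInf <- s * adductsPerBase
  nBg <- d - nInf
  cls <- rep(1:2, length.out = m)
  noiseScale <- rep(1, m)
  nOut <- round(outlierSampleFrac * m)
  outliers <- if (nOut > 0) sort(sample.int(m, nOut)) else integer(0)
  noiseScale[outliers] <- outlierScale
  L <- matrix(0, m, d)
  effect <- log2FoldChange * log10(2)
  infIds <- character(nInf)
  blockMap <- vector("list", s)
  names(blockMap) <- sprintf("MET%02d", seq_len(s))
  col <- 0L
  for (i in seq_len(s)) {
    baseMean <- stats::runif(1, baseLog10MeanRange[1], baseLog10MeanRange[2])
    baseSignal <- baseMean + ifelse(cls == 2L, effect, 0) +
      stats::rnorm(m, 0, featureSdLog10) * noiseScale
    offsets <- stats::rnorm(adductsPerBase, 0, 0.3)
    members <- character(adductsPerBase)
    for (a in seq_len(adductsPerBase)) {
      col <- col + 1L
      L[, col] <- baseSignal + offsets[a] +
        stats::rnorm(m, 0, adductJitterSd) * noiseScale
      members[a] <- sprintf("MET%02d_ADD%d", i, a)
      infIds[col] <- members[a]
    }
    blockMap[[i]] <- members
  }
  bgIds <- sprintf("BG%04d", seq_len(nBg))
  for (j in seq_len(nBg)) {
    col <- col + 1L
    mn <- stats::runif(1, baseLog10MeanRange[1], baseLog10MeanRange[2])
    L[, col] <- mn + stats::rnorm(m, 0, featureSdLog10) * noiseScale
  }
  featIds <- c(infIds, bgIds)
  perm <- sample.int(d)
  L <- L[, perm, drop = FALSE]
  featIds <- featIds[perm]
  values <- 10^L
  if (dropoutProb > 0)
    values[stats::runif(m * d) < dropoutProb] <- 0
  dimnames(values) <- list(sprintf("S%03d", seq_len(m)), featIds)
  labels <- encodeLabels(paste0("class", cls))
  list(
    table = MetaboTable(values, stage = "raw"),
    truth = list(
      labels = labels,
      informativeFeatureIds = infIds,
      blockMap = blockMap,
      outlierSamples = sprintf("S%03d", outliers),
      settings = list(m = m, d = d, s = s, adductsPerBase = adductsPerBase,
                      log2FoldChange = log2FoldChange,
                      baseLog10MeanRange = baseLog10MeanRange,
                      featureSdLog10 = featureSdLog10,
                      adductJitterSd = adductJitterSd,
                      dropoutProb = dropoutProb,
                      outlierSampleFrac = outlierSampleFrac,
                      outlierScale = outlierScale, seed = seed)
    )
  )
}

#' Within-block correlation of adduct features
#'
#' Mean pairwise Pearson correlation of log10 intensities within each
#' planted adduct block; a sanity check that the generator produces the
#' intended correlated feature structure. Requires a table generated with
#' \code{dropoutProb = 0} (zeros have no log).
#'
#' @param table a raw \linkS4class{MetaboTable} from
#'   \code{\link{simulateMetabolomics}}.
#' @param truth the matching \code{truth} list.
#' @return Named numeric vector of per-block mean correlations (blocks of
#'   size 1 are skipped).
#' @export
blockCorrelation <- function(table, truth) {
  v <- intensityMatrix(table)
  if (any(v <= 0))
    stop("blockCorrelation needs a dropout-free table (all values > 0)")
  lv <- log10(v)
  out <- numeric(0)
  for (nm in names(truth$blockMap)) {
    members <- truth$blockMap[[nm]]
    if (length(members) < 2L) next
    cm <- stats::cor(lv[, members, drop = FALSE])
    out[nm] <- mean(cm[upper.tri(cm)])
  }
  out
}
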