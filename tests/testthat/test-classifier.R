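# manual two-feature model with identity-like geometry: scaled value of a
# raw intensity x is simply log10(x), so test samples can be placed exactly
makeToyModel <- function(W = diag(2), mu = diag(2),
                         classNames = c("A", "B"), eta = 2) {
  new("PdcrModel", W = W, mu = mu, classNames = classNames,
      featureIds = c("f1", "f2"), trainingFeatureIds = c("f1", "f2"),
      scaling = new("ScalingParams", means = c(f1 = 0, f2 = 0),
                    scales = c(f1 = 1, f2 = 1), pseudocount = 0,
                    logBase = 10),
      config = solverConfig(eta = eta), minFraction = 0,
      iterationsRun = 1L, converged = TRUE)
}

test_that("centroid distances follow the l1 formula and permute with classes", {
  mod <- makeToyModel()
  expect_equal(distancesToCentroids(mod, c(1, 0)), c(A = 0, B = 2))
  expect_equal(distancesToCentroids(mod, c(0.5, 0.5)), c(A = 1, B = 1))
  # W = 0: every sample sits at the origin, each one-hot centroid at l1
  # distance 1
  mod0 <- makeToyModel(W = matrix(0, 2, 2))
  expect_equal(distancesToCentroids(mod0, rnorm(2)), c(A = 1, B = 1))
  # permuting centroid rows permutes the distances identically
  modP <- makeToyModel(mu = diag(2)[c(2, 1), ])
  x <- c(0.3, -0.8)
  expect_equal(unname(distancesToCentroids(modP, x)),
               unname(distancesToCentroids(mod, x))[c(2, 1)])
  expect_error(distancesToCentroids(mod, 1:3), "features")
})

test_that("prediction applies stored transforms, argmin and CSP rules", {
  mod <- makeToyModel()
  tab <- makeRawTable(rbind(c(10, 1),    # scaled (1,0): exactly centroid A
                            c(1, 10),    # centroid B
                            c(sqrt(10), sqrt(10))),  # equidistant
                      featureIds = c("f1", "f2"))
  pr <- predict(mod, tab)
  expect_equal(pr$predictedClass, c("A", "B", "A"))  # tie -> lowest index
  expect_equal(pr$csp, c(-1, 1, 0))
  expect_equal(pr$d_1, c(0, 2, 1))
  expect_equal(pr$finalLabel, pr$predictedClass)     # epsilon = 0
  # feature-column permutation of the input changes nothing
  prPerm <- predict(mod, tab[c(2, 1), ])
  expect_equal(prPerm, pr)
  # unknown features are an error, never dropped
  bad <- tab
  rownames(bad)[1] <- "f_unknown"
  expect_error(predict(mod, bad), "mismatch.*f_unknown|f_unknown")
  expect_error(predict(mod, logTransform(tab)), "raw-stage")
})

test_that("binary CSP takes values in [-1,1] with the documented sign", {
  expect_equal(cspBinary(0, 4), -1)
  expect_equal(cspBinary(3, 3), 0)
  expect_equal(cspBinary(3, 1), 0.5)
  expect_warning(z <- cspBinary(0, 0), "degenerate")
  expect_equal(z, 0)
  set.seed(21)
  d1 <- rexp(500); d2 <- rexp(500)
  r <- cspBinary(d1, d2)
  expect_true(all(r >= -1 & r <= 1))
  expect_true(all((r < 0) == (d1 < d2)))
  expect_error(cspBinary(-1, 2), "nonnegative")
})

test_that("multi-class CSP is in [0,1] and collapses to |binary CSP| at k=2", {
  expect_equal(cspMulticlass(c(0, 1, 1)), 1)
  expect_equal(cspMulticlass(c(2, 2, 2, 2)), 0)
  expect_equal(cspMulticlass(c(1, 3)), 0.5)
  expect_warning(z <- cspMulticlass(c(0, 0)), "degenerate")
  expect_equal(z, 1)
  set.seed(22)
  for (i in 1:200) {
    d <- rexp(2)
    expect_equal(cspMulticlass(d), abs(cspBinary(d[1], d[2])),
                 tolerance = 1e-12)
  }
})

test_that("rejection rule keeps strict inequalities and grows with epsilon", {
  pr <- data.frame(sampleId = letters[1:4],
                   predictedClass = c("B", "A", "B", "A"),
                   csp = c(0.5, -0.1, 0.3, -0.9))
  out <- predictWithRejection(pr, 0.3)
  expect_equal(out$finalLabel, c("B", "rejected", "B", "A"))
  expect_false(out$rejected[3])         # |csp| == epsilon: classified
  expect_equal(predictWithRejection(pr, 0)$finalLabel, pr$predictedClass)
  # monotone rejected sets
  prev <- rep(FALSE, 4)
  for (eps in seq(0, 1, by = 0.05)) {
    cur <- predictWithRejection(pr, eps)$rejected
    expect_true(all(cur[prev]))                    # inclusion
    prev <- cur
  }
  expect_error(predictWithRejection(pr, 1.2), "epsilon")
})

test_that("fitting is deterministic, feasible and learns separable data", {
  sim <- simulateMetabolomics(m = 40, d = 120, s = 5, seed = 9)
  cfg <- solverConfig(eta = 2)
  fit <- pdcrFit(sim$table, sim$truth$labels, cfg)
  expect_lte(sum(abs(projectionMatrix(fit))), 2 + 1e-9)
  pr <- predict(fit, sim$table)
  truth <- decodeLabels(sim$truth$labels)
  expect_gte(accuracyScore(pr$predictedClass, truth), 0.95)
  # binary CSP sign is consistent with the argmin rule
  expect_true(all((pr$csp < 0) == (pr$predictedClass == "class1") |
                  pr$csp == 0))
  fit2 <- pdcrFit(sim$table, sim$truth$labels, cfg)
  expect_identical(projectionMatrix(fit), projectionMatrix(fit2))
  expect_identical(centroids(fit), centroids(fit2))
  expect_identical(predict(fit2, sim$table), pr)
  expect_warning(pdcrFit(sim$table, sim$truth$labels, solverConfig(eta = 0)),
                 "eta = 0")
})

test_that("feature ranking scores rows of W and flags unselected features", {
  W <- rbind(c(0.5, -0.25), c(0, 0))
  mod <- makeToyModel(W = W)
  rk <- featureRanking(mod)
  expect_equal(rk$featureId, c("f1", "f2"))
  expect_equal(rk$score, c(0.75, 0))
  expect_equal(rk$selected, c(TRUE, FALSE))
  mod0 <- makeToyModel(W = matrix(0, 2, 2))
  expect_message(rk0 <- featureRanking(mod0), "no features selected")
  expect_true(all(rk0$score == 0))
  # planted informative features dominate the ranking on clean data with a
  # strong (8-fold) effect
  sim <- simulateMetabolomics(m = 40, d = 120, s = 5, seed = 10,
                              dropoutProb = 0, log2FoldChange = 3)
  fit <- pdcrFit(sim$table, sim$truth$labels, solverConfig(eta = 5))
  top <- head(featureRanking(fit)$featureId, 15)
  expect_gte(mean(sim$truth$informativeFeatureIds %in% top), 0.8)
})

test_that("model JSON serialization round-trips to identical predictions", {
  sim <- simulateMetabolomics(m = 30, d = 60, s = 4, seed = 11)
  fit <- pdcrFit(sim$table, sim$truth$labels, solverConfig(eta = 1.5))
  path <- tempfile(fileext = ".json")
  writePdcrModel(fit, path)
  back <- readPdcrModel(path)
  expect_identical(projectionMatrix(back), projectionMatrix(fit))
  expect_identical(centroids(back), centroids(fit))
  expect_identical(predict(back, sim$table), predict(fit, sim$table))
})

test_that("three-class fitting and prediction use the multi-class CSP", {
  set.seed(33)
  m <- 30; d <- 12
  cls <- rep(1:3, each = 10)
  centers <- matrix(c(4, 3, 3, 3, 4, 3, 3, 3, 4), 3, 3)[cls, ]
  v <- 10^(cbind(centers, matrix(3.5, m, 0))[, rep(1:3, each = 4)] +
             matrix(rnorm(m * d, 0, 0.15), m, d))
  tab <- makeRawTable(v)
  labels <- paste0("g", cls)
  fit <- pdcrFit(tab, labels, solverConfig(eta = 3))
  expect_equal(classNames(fit), c("g1", "g2", "g3"))
  pr <- predict(fit, tab, epsilon = 0.1)
  expect_named(pr, c("sampleId", "d_1", "d_2", "d_3", "predictedClass",
                     "csp", "rejected", "finalLabel"))
  expect_true(all(pr$csp >= 0 & pr$csp <= 1))
  expect_gte(accuracyScore(pr$predictedClass, labels), 0.9)
  expect_true(all(pr$finalLabel[!pr$rejected] ==
                    pr$predictedClass[!pr$rejected]))
  cv <- pdcrCrossValidate(tab, labels, folds = 3, seeds = 0,
                          config = solverConfig(eta = 3))
  expect_true(is.na(cv@meanAuc))       # AUC is a binary-task metric
  expect_gte(cv@meanAccuracy, 0.8)
})
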