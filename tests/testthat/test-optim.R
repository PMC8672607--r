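test_that("Huber function matches its piecewise definition and l1 bound", {
  expect_equal(huberValue(0.5, 1), 0.125)
  expect_equal(huberValue(2, 1), 1.5)
  expect_equal(huberValue(1, 1), 0.5)          # continuity at |t| = delta
  expect_equal(huberValue(-1, 1), 0.5)
  grid <- seq(-5, 5, by = 0.01)
  for (delta in c(0.05, 0.3, 1, 2)) {
    h <- huberValue(grid, delta)
    expect_true(all(h >= 0))
    expect_true(all(h <= abs(grid) + 1e-12))
    expect_true(all(abs(h - abs(grid)) <= delta / 2 + 1e-12))
  }
  expect_error(huberValue(1, 0), "delta")
})

test_that("Huber dual prox is the shrink-then-clip resolvent", {
  expect_equal(huberDualProx(0, 1, 1), 0)
  expect_equal(huberDualProx(10, 1, 1), 1)
  expect_equal(huberDualProx(-10, 2, 0.5), -1)
  # numerical prox oracle: argmin_u (u - z)^2 / 2 + sigma * delta * u^2 / 2
  # over u in [-1, 1] (the Huber conjugate is delta u^2/2 on [-1,1])
  set.seed(7)
  for (i in 1:50) {
    z <- rnorm(1, sd = 2)
    sigma <- runif(1, 0.1, 3)
    delta <- runif(1, 0.1, 2)
    num <- optimize(function(u) (u - z)^2 / 2 + sigma * delta * u^2 / 2,
                    c(-1, 1), tol = 1e-12)$minimum
    expect_equal(huberDualProx(z, sigma, delta), num, tolerance = 1e-6)
  }
  # entries always land in [-1, 1]
  Z <- matrix(rnorm(40, sd = 5), 8, 5)
  expect_true(all(abs(huberDualProx(Z, 0.7, 0.3)) <= 1))
})

test_that("l1-ball projection matches the KKT bisection oracle", {
  expect_equal(projectL1Ball(c(2, 0), 1), c(1, 0))
  expect_equal(projectL1Ball(c(1, 1), 1), c(0.5, 0.5))
  v <- c(0.3, -0.2)                      # interior point: unchanged
  expect_identical(projectL1Ball(v, 1), v)
  expect_equal(projectL1Ball(c(3, -4), 0), c(0, 0))
  expect_error(projectL1Ball(1, -0.1), "eta")

  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    v <- rnorm(n, sd = 2)
    eta <- runif(1, 0, 4)
    p <- projectL1Ball(v, eta)
    expect_equal(p, oracleProjectL1(v, eta), tolerance = 1e-10)
    expect_lte(sum(abs(p)), eta + 1e-12)
    expect_true(all(sign(p[p != 0]) == sign(v[p != 0])))
    expect_equal(projectL1Ball(p, eta), p, tolerance = 1e-12)  # idempotent
  }
})

test_that("l1-ball projection is non-expansive and beats any grid point", {
  set.seed(12)
  for (i in 1:50) {
    u <- rnorm(4, sd = 2); v <- rnorm(4, sd = 2)
    eta <- runif(1, 0.5, 3)
    pu <- projectL1Ball(u, eta); pv <- projectL1Ball(v, eta)
    expect_lte(sqrt(sum((pu - pv)^2)), sqrt(sum((u - v)^2)) + 1e-12)
  }
  # dense grid over the 2d ball: no feasible point is closer than the
  # returned projection
  v <- c(1.7, -0.9)
  p <- projectL1Ball(v, 1)
  g <- as.matrix(expand.grid(x = seq(-1, 1, by = 0.002),
                             y = seq(-1, 1, by = 0.002)))
  g <- g[abs(g[, 1]) + abs(g[, 2]) <= 1, ]
  dmin <- min(colSums((t(g) - v)^2))
  expect_lte(sum((p - v)^2), dmin + 1e-9)
})

test_that("operator norm estimate agrees with closed forms and SVD", {
  # X = 0, one-hot Y with each class once: singular values of Y are all 1
  Y <- diag(3)
  X <- matrix(0, 3, 4)
  expect_equal(estimateOperatorNorm(X, Y), 1, tolerance = 1e-8)
  # Y = 0, X = c I: norm is c
  expect_equal(estimateOperatorNorm(3.5 * diag(4), matrix(0, 4, 2)), 3.5,
               tolerance = 1e-8)
  set.seed(13)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 10), 20, 10)
    Y <- matrix(0, 20, 2); Y[cbind(1:20, rep(1:2, 10))] <- 1
    expect_equal(estimateOperatorNorm(X, Y, iters = 500L),
                 svd(cbind(X, Y))$d[1], tolerance = 1e-6)
  }
  expect_error(estimateOperatorNorm(diag(2), diag(2), iters = 0L), "iters")
})

test_that("objective matches a straight-line recomputation", {
  inst <- makeTinyInstance(1)
  cfg <- solverConfig(delta = 0.4, rhoPenalty = 1.3)
  k <- ncol(inst$Y); m <- nrow(inst$Y)
  # W = 0, mu = I: one unit entry per row of Y
  expect_equal(pdcrObjective(matrix(0, ncol(inst$X), k), diag(k),
                             inst$X, inst$Y, cfg),
               m * huberValue(1, 0.4))
  # exact fit with mu = I: objective 0
  Xid <- rbind(diag(2), diag(2))
  Yid <- rbind(diag(2), diag(2))
  expect_equal(pdcrObjective(diag(2), diag(2), Xid, Yid, cfg), 0)
  set.seed(14)
  for (i in 1:10) {
    W <- matrix(rnorm(ncol(inst$X) * k), ncol = k)
    mu <- matrix(rnorm(k * k), k, k)
    expect_equal(pdcrObjective(W, mu, inst$X, inst$Y, cfg),
                 oracleObjective(W, mu, inst$X, inst$Y, 0.4, 1.3))
  }
  expect_error(pdcrObjective(matrix(0, 2, 2), diag(2), inst$X, inst$Y, cfg),
               "shapes")
})

test_that("solver stays feasible, beats the reference point and is deterministic", {
  inst <- makeTinyInstance(2)
  cfg <- solverConfig(eta = 1.5, maxIter = 5000L, tol = 1e-10)
  sol <- pdSolve(inst$X, inst$Y, cfg)
  expect_lte(sol@maxL1Norm, 1.5 + 1e-9)
  ref <- pdcrObjective(matrix(0, ncol(inst$X), 2), diag(2),
                       inst$X, inst$Y, cfg)
  expect_lte(pdcrObjective(sol@W, sol@mu, inst$X, inst$Y, cfg), ref)
  sol2 <- pdSolve(inst$X, inst$Y, cfg)
  expect_identical(sol@W, sol2@W)
  expect_identical(sol@mu, sol2@mu)
})

test_that("eta = 0 forces W = 0 and mu matches the decoupled closed form", {
  inst <- makeTinyInstance(3, m = 10L)
  nj <- colSums(inst$Y)
  delta <- 0.3; rho <- 1
  cfg <- solverConfig(delta = delta, rhoPenalty = rho, eta = 0,
                      maxIter = 20000L, tol = 1e-12)
  sol <- pdSolve(inst$X, inst$Y, cfg)
  expect_true(all(sol@W == 0))
  muStar <- diag(rho / (nj / delta + rho))   # quadratic-branch optimum
  expect_lt(max(abs(sol@mu - muStar)), 1e-5)
  # quadratic-branch validity: all fitted responses inside the knee
  expect_true(all(abs(inst$Y %*% sol@mu) <= delta))
})

test_that("solver objective is non-increasing in eta (nested feasible sets)", {
  inst <- makeTinyInstance(4)
  objs <- vapply(c(0, 0.5, 1, 2, 1000), function(eta) {
    cfg <- solverConfig(eta = eta, maxIter = 20000L, tol = 1e-12)
    sol <- pdSolve(inst$X, inst$Y, cfg)
    pdcrObjective(sol@W, sol@mu, inst$X, inst$Y, cfg)
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-6))
})

test_that("duplicated feature columns share the weight of the single column", {
  inst <- makeTinyInstance(5, d = 4L)
  Xdup <- cbind(inst$X, inst$X[, 2])
  cfg <- solverConfig(eta = 1, maxIter = 50000L, tol = 1e-13)
  solA <- pdSolve(inst$X, inst$Y, cfg)
  solB <- pdSolve(Xdup, inst$Y, cfg)
  wSingle <- solA@W[2, ]
  wPair <- solB@W[2, ] + solB@W[5, ]
  expect_lt(max(abs(wPair - wSingle)), 1e-3)
  expect_true(solB@converged)
})

test_that("squared_l2 loss equals Huber's quadratic branch scaled by delta", {
  inst <- makeTinyInstance(6)
  bigDelta <- 1e3
  cfgL2 <- solverConfig(eta = 1, loss = "squared_l2", maxIter = 3000L)
  sol <- pdSolve(inst$X, inst$Y, cfgL2)
  R <- inst$Y %*% sol@mu - inst$X %*% sol@W
  expect_true(all(abs(R) < bigDelta))        # every residual in the knee
  expect_equal(sum(huberValue(R, bigDelta)) * bigDelta, 0.5 * sum(R^2))
  # dual prox of the l2 loss has no clipping: values may exceed 1
  cfgH <- solverConfig(eta = 1, loss = "huber", maxIter = 3000L)
  solH <- pdSolve(inst$X, inst$Y, cfgH)
  expect_false(identical(sol@W, solH@W))
})
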