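# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: projection by bisection instead of sorting,
# optimization by projected FISTA instead of the primal-dual scheme, AUC by
# exhaustive pair counting instead of ranks.

oracleHuber <- function(t, delta) {
  ifelse(abs(t) <= delta, t^2 / (2 * delta), abs(t) - delta / 2)
}

# Euclidean projection onto {v: sum|v| <= eta} via bisection on the
# soft-threshold level (KKT characterization)
oracleProjectL1 <- function(v, eta) {
  a <- abs(v)
  if (sum(a) <= eta) return(v)
  if (eta == 0) return(v * 0)
  f <- function(theta) sum(pmax(a - theta, 0)) - eta
  theta <- stats::uniroot(f, c(0, max(a)), tol = 1e-14)$root
  sign(v) * pmax(a - theta, 0)
}

oracleObjective <- function(W, mu, X, Y, delta, rho) {
  R <- Y %*% mu - X %*% W
  sum(oracleHuber(R, delta)) + rho / 2 * sum((diag(ncol(Y)) - mu)^2)
}

# gradient of the smooth objective (Huber is C1)
.oracleGrad <- function(W, mu, X, Y, delta, rho) {
  R <- Y %*% mu - X %*% W
  G <- ifelse(abs(R) <= delta, R / delta, sign(R))
  list(W = -crossprod(X, G),
       mu = crossprod(Y, G) + rho * (mu - diag(ncol(Y))))
}

# Long-run projected accelerated gradient (FISTA) on the same criterion:
# smooth part has Lipschitz gradient with L <= ||A||^2/delta + rho.
oracleSolve <- function(X, Y, delta, rho, eta, iters = 30000L) {
  d <- ncol(X); k <- ncol(Y)
  L <- (svd(cbind(X, Y))$d[1])^2 / delta + rho
  step <- 1 / L
  W <- Wp <- matrix(0, d, k)
  mu <- mup <- diag(k)
  tAcc <- 1
  for (i in seq_len(iters)) {
    g <- .oracleGrad(W, mu, X, Y, delta, rho)
    Wn <- oracleProjectL1(W - step * g$W, eta)
    mun <- mu - step * g$mu
    tNew <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
    W <- Wn + (tAcc - 1) / tNew * (Wn - Wp)
    mu <- mun + (tAcc - 1) / tNew * (mun - mup)
    # momentum point may leave the ball; keep the feasible iterate separately
    Wp <- Wn; mup <- mun
    tAcc <- tNew
  }
  list(W = Wp, mu = mup,
       objective = oracleObjective(Wp, mup, X, Y, delta, rho))
}

oracleAuc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# random tiny classification instance for solver cross-checks
makeTinyInstance <- function(seed, m = 8L, d = 5L, k = 2L) {
  set.seed(seed)
  cls <- sort(rep_len(seq_len(k), m))
  Y <- matrix(0, m, k)
  Y[cbind(seq_len(m), cls)] <- 1
  X <- matrix(rnorm(m * d), m, d) + 0.8 * Y %*% matrix(rnorm(k * d), k, d)
  X <- scale(X)
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  list(X = X, Y = Y, cls = cls)
}

# small raw MetaboTable fixture
makeRawTable <- function(values, sampleIds = NULL, featureIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(featureIds)) featureIds <- sprintf("f%02d", seq_len(ncol(values)))
  MetaboTable(values, sampleIds = sampleIds, featureIds = featureIds)
}
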