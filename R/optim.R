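#' Huber function
#'
#' The robust loss used by the solver: quadratic \code{t^2 / (2 delta)} for
#' \code{|t| <= delta}, linear \code{|t| - delta/2} beyond. It interpolates
#' between the squared-l2 loss (large \code{delta}) and the l1 loss
#' (\code{delta -> 0}), staying differentiable everywhere.
#'
#' @param t numeric vector or matrix; applied entrywise.
#' @param delta positive knee parameter.
#' @return Elementwise Huber values, same shape as \code{t}.
#' @examples
#' huberValue(c(0.5, 2), delta = 1)  # 0.125, 1.5
#' @export
huberValue <- function(t, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive scalar")
  a <- abs(t)
  ifelse(a <= delta, t^2 / (2 * delta), a - delta / 2)
}

#' Proximal operator of the scaled Huber conjugate
#'
#' Resolvent of \code{sigma * h_delta^*} applied entrywise: the dual update
#' of the primal-dual iteration. For the Huber function the conjugate is
#' \code{delta z^2 / 2} on \code{[-1, 1]} (+infinity outside), so the prox
#' is a shrink-then-clip: \code{z / (1 + sigma * delta)} clipped to
#' \code{[-1, 1]}.
#'
#' @param z numeric vector or matrix of dual variables.
#' @param sigma positive dual step size.
#' @param delta positive Huber knee.
#' @return Same shape as \code{z}, entries in \code{[-1, 1]}.
#' @export
huberDualProx <- function(z, sigma, delta) {
  if (sigma <= 0) stop("sigma must be positive")
  if (delta <= 0) stop("delta must be positive")
  pmin(pmax(z / (1 + sigma * delta), -1), 1)
}

#' Euclidean projection onto the l1 ball
#'
#' Exact sort-based projection of a vector or matrix onto
#' \code{\{v : sum(|v|) <= eta\}} (entrywise l1 norm for matrices). Interior
#' points are returned unchanged; otherwise the standard cumulative-sum
#' threshold is computed in O(n log n) and entries are soft-thresholded,
#' preserving the sign pattern.
#'
#' @param v numeric vector or matrix.
#' @param eta nonnegative radius.
#' @return The projection, same shape as \code{v}.
#' @examples
#' projectL1Ball(c(2, 0), 1)  # c(1, 0)
#' projectL1Ball(c(1, 1), 1)  # c(0.5, 0.5)
#' @export
projectL1Ball <- function(v, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) || eta < 0)
    stop("eta must be a nonnegative scalar")
  a <- abs(v)
  if (sum(a) <= eta) return(v)
  if (eta == 0) {
    v[] <- 0
    return(v)
  }
  u <- sort(as.numeric(a), decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u > (css - eta) / j])
  theta <- (css[rho] - eta) / rho
  v[] <- sign(v) * pmax(a - theta, 0)
  v
}

#' Operator norm of the residual map
#'
#' Estimates the spectral norm of the linear map
#' \code{A(W, mu) = Y mu - X W} by power iteration. Because the map acts
#' column-by-column as \code{cbind(-X, Y)}, its norm is the largest singular
#' value of \code{cbind(X, Y)}; the power iteration runs on that matrix's
#' Gram operator without forming it. Deterministic for a given \code{seed}.
#'
#' @param X m x d data matrix.
#' @param Y m x k label matrix.
#' @param iters number of power iterations (default 100).
#' @param seed integer seed for the random start vector.
#' @return The estimated operator norm (positive scalar).
#' @export
estimateOperatorNorm <- function(X, Y, iters = 100L, seed = 0L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L) stop("matrices must be nonempty")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (iters < 1L) stop("iters must be >= 1")
  n <- ncol(X) + ncol(Y)
  # private RNG stream: don't disturb the caller's seed state
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  v <- stats::rnorm(n)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  v <- v / sqrt(sum(v^2))
  dX <- ncol(X)
  nrm <- 0
  for (i in seq_len(iters)) {
    w <- X %*% v[seq_len(dX)] + Y %*% v[-seq_len(dX)]
    v2 <- c(crossprod(X, w), crossprod(Y, w))
    nrm <- sqrt(sum(v2^2))
    if (nrm == 0) return(0)
    v <- v2 / nrm
  }
  sqrt(nrm)
}

#' Objective of the constrained centroid criterion
#'
#' Evaluates \code{sum h_delta(Y mu - X W) + rhoPenalty/2 * ||I_k - mu||_F^2}
#' (with the Huber sum replaced by \code{0.5 * ||.||_F^2} when
#' \code{loss = "squared_l2"}). The l1-ball constraint on W is not part of
#' the value; feasibility is enforced by the solver.
#'
#' @param W d x k projection matrix.
#' @param mu k x k centroid matrix.
#' @param X m x d scaled data matrix.
#' @param Y m x k one-hot label matrix.
#' @param config a \linkS4class{SolverConfig} (delta, rhoPenalty, loss).
#' @return Nonnegative scalar objective value.
#' @export
pdcrObjective <- function(W, mu, X, Y, config) {
  stopifnot(is(config, "SolverConfig"))
  W <- as.matrix(W); mu <- as.matrix(mu)
  X <- as.matrix(X); Y <- as.matrix(Y)
  k <- ncol(Y)
  if (ncol(X) != nrow(W) || ncol(W) != k || any(dim(mu) != k) ||
      nrow(X) != nrow(Y))
    stop("inconsistent shapes in objective evaluation")
  R <- Y %*% mu - X %*% W
  lossVal <- if (config@loss == "huber")
    sum(huberValue(R, config@delta)) else 0.5 * sum(R^2)
  lossVal + config@rhoPenalty / 2 * sum((diag(k) - mu)^2)
}

#' Primal-dual solver for the sparse centroid criterion
#'
#' Minimizes \code{h_delta(Y mu - X W) + rhoPenalty/2 ||I_k - mu||_F^2}
#' subject to \code{||W||_1 <= eta} with a Chambolle-Pock primal-dual
#' iteration with extrapolation:
#' \preformatted{
#'   Z   <- prox_{sigma h*}(Z + sigma (Y mubar - X Wbar))
#'   W+  <- project_l1(W + tau X' Z, eta)
#'   mu+ <- (mu - tau Y' Z + tau rho I_k) / (1 + tau rho)
#'   (Wbar, mubar) <- 2 (W+, mu+) - (W, mu)
#' }
#' Initialization is deterministic (W = 0, mu = I_k, Z = 0). With
#' \code{autoSteps} the steps are \code{sigma = tau = 0.99 / ||A||}, which
#' satisfies the convergence condition \code{sigma tau ||A||^2 <= 1}. Every
#' iterate is primal-feasible by construction of the projection. The
#' iteration stops when the relative change of \code{(W, mu)} falls below
#' \code{tol} or after \code{maxIter} iterations; the objective trace is
#' recorded for diagnostics only (primal-dual objectives are not monotone).
#'
#' @param X m x d scaled data matrix.
#' @param Y m x k one-hot label matrix (or a \linkS4class{ClassLabels}).
#' @param config a \linkS4class{SolverConfig}.
#' @return A \linkS4class{PdcrSolution}.
#' @export
pdSolve <- function(X, Y, config = solverConfig()) {
  stopifnot(is(config, "SolverConfig"))
  validObject(config)
  if (is(Y, "ClassLabels")) Y <- Y@onehot
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); d <- ncol(X); k <- ncol(Y)
  if (nrow(Y) != m) stop("X and Y must have the same number of rows")
  if (!all(Y %in% c(0, 1)) || !all(rowSums(Y) == 1))
    stop("Y must be a one-hot indicator matrix")
  sigma <- config@sigma; tau <- config@tau
  if (config@autoSteps || is.na(sigma) || is.na(tau)) {
    nrmA <- estimateOperatorNorm(X, Y, iters = 200L, seed = 0L)
    if (nrmA == 0) nrmA <- 1
    sigma <- tau <- 0.99 / nrmA
  }
  delta <- config@delta; rho <- config@rhoPenalty; eta <- config@eta
  Ik <- diag(k)
  W <- matrix(0, d, k, dimnames = list(colnames(X), colnames(Y)))
  mu <- Ik
  Z <- matrix(0, m, k)
  Wbar <- W; mubar <- mu
  trace <- numeric(config@maxIter)
  maxL1 <- 0
  converged <- FALSE
  it <- 0L
  dualShrink <- if (config@loss == "huber") 1 + sigma * delta else 1 + sigma
  clipDual <- config@loss == "huber"
  for (it in seq_len(config@maxIter)) {
    Z <- (Z + sigma * (Y %*% mubar - X %*% Wbar)) / dualShrink
    if (clipDual) Z <- pmin(pmax(Z, -1), 1)
    Wnew <- projectL1Ball(W + tau * crossprod(X, Z), eta)
    munew <- (mu - tau * crossprod(Y, Z) + tau * rho * Ik) / (1 + tau * rho)
    if (!all(is.finite(Wnew)) || !all(is.finite(munew)))
      stop("non-finite values encountered at iteration ", it,
           "; consider smaller step sizes")
    Wbar <- 2 * Wnew - W
    mubar <- 2 * munew - mu
    num <- sqrt(sum((Wnew - W)^2) + sum((munew - mu)^2))
    den <- max(1, sqrt(sum(W^2) + sum(mu^2)))
    W <- Wnew; mu <- munew
    maxL1 <- max(maxL1, sum(abs(W)))
    trace[it] <- pdcrObjective(W, mu, X, Y, config)
    if (num / den < config@tol) {
      converged <- TRUE
      break
    }
  }
  new("PdcrSolution", W = W, mu = mu, objectiveTrace = trace[seq_len(it)],
      iterationsRun = it, converged = converged, maxL1Norm = maxL1)
}
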