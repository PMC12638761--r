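#' @include genetics.R
NULL

#' Elastic-net penalty configuration
#'
#' @param alpha L1 fraction of the penalty; 0.5 = balanced elastic net
#'   (default, matching the mediation analyses), 1 = lasso, 0 = ridge.
#' @param k cross-validation folds (default 10).
#' @param nLambda grid size (default 100, log-spaced).
#' @param lambdaMinRatio smallest grid lambda as a fraction of the smallest
#'   lambda that zeroes all penalized coefficients (default 1e-4).
#' @param tol coordinate-descent convergence tolerance on the maximum
#'   coefficient change per sweep (default 1e-7).
#' @param maxit maximum coordinate-descent sweeps per lambda (default 1e5).
#' @param seed RNG seed for the fold assignment.
#' @return list of class parameters used by [elasticNet()] and [xmed()].
#' @export
penaltyConfig <- function(alpha = 0.5, k = 10, nLambda = 100,
                          lambdaMinRatio = 1e-4, tol = 1e-7, maxit = 1e5,
                          seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, k >= 2)
  list(alpha = alpha, k = k, nLambda = nLambda,
       lambdaMinRatio = lambdaMinRatio, tol = tol,
       maxit = as.integer(maxit), seed = as.integer(seed))
}

# log-spaced lambda grid from lambda_max down to lambda_max * minRatio
.lambdaGrid <- function(X, y, alpha, nLambda, minRatio) {
  n <- nrow(X)
  aEff <- max(alpha, 1e-3)  # ridge never zeroes; use a nominal grid anchor
  lamMax <- max(abs(crossprod(X, y))) / (n * aEff)
  lamMax <- max(lamMax, 1e-8)
  exp(seq(log(lamMax), log(lamMax * minRatio), length.out = nLambda))
}

# covariance-form path fit; returns p x nlambda coefficient matrix
.enetPath <- function(X, y, lambda, alpha, tol = 1e-7, maxit = 1e5) {
  n <- nrow(X)
  G <- crossprod(X) / n
  cvec <- drop(crossprod(X, y)) / n
  fit <- .enetCdPath(G, cvec, lambda, alpha, tol, as.integer(maxit))
  if (!all(fit$converged)) {
    warning("coordinate descent hit the sweep limit for some lambda values")
  }
  fit$beta
}

#' Elastic-net regression by coordinate descent
#'
#' Minimizes \eqn{\frac{1}{2N} ||y - X\beta||^2 + \lambda (\alpha
#' ||\beta||_1 + \frac{1-\alpha}{2} ||\beta||_2^2)} by cyclic coordinate
#' descent in covariance form, warm-started along a decreasing lambda path.
#' Inputs are expected standardized (the mediation pipeline z-scores
#' everything first); no intercept is fitted. When \code{lambda} is NULL the
#' penalty weight is chosen by k-fold cross-validation at the minimum mean
#' squared prediction error.
#'
#' @param X numeric predictor matrix (standardized columns).
#' @param y numeric response (centered/standardized).
#' @param penalty a [penaltyConfig()].
#' @param lambda optional fixed lambda (scalar or vector); overrides CV.
#' @return list with \code{coef} (vector at the chosen lambda),
#'   \code{lambda} (chosen value), \code{lambdaGrid}, \code{cvError} (mean
#'   CV error per grid lambda, NULL when lambda was fixed) and \code{path}
#'   (p x nLambda coefficients).
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(200 * 5), 200))
#' y <- drop(X %*% c(1, -0.5, 0, 0, 0)) + rnorm(200)
#' fit <- elasticNet(X, y, penaltyConfig(alpha = 0.5, k = 5))
#' fit$coef
#' @export
elasticNet <- function(X, y, penalty = penaltyConfig(), lambda = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (!is.null(lambda)) {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
    path <- .enetPath(X, y, lambda, penalty$alpha, penalty$tol, penalty$maxit)
    sel <- length(lambda)  # smallest requested lambda
    return(list(coef = path[, sel], lambda = lambda[sel],
                lambdaGrid = lambda, cvError = NULL, path = path))
  }
  grid <- .lambdaGrid(X, y, penalty$alpha, penalty$nLambda,
                      penalty$lambdaMinRatio)
  folds <- .cvFolds(length(y), penalty$k, penalty$seed)
  cvErr <- matrix(0, penalty$k, length(grid))
  for (f in seq_len(penalty$k)) {
    test <- folds == f
    beta <- .enetPath(X[!test, , drop = FALSE], y[!test], grid,
                      penalty$alpha, penalty$tol, penalty$maxit)
    pred <- X[test, , drop = FALSE] %*% beta
    cvErr[f, ] <- colMeans((y[test] - pred)^2)
  }
  mErr <- colMeans(cvErr)
  best <- which.min(mErr)
  path <- .enetPath(X, y, grid, penalty$alpha, penalty$tol, penalty$maxit)
  list(coef = path[, best], lambda = grid[best], lambdaGrid = grid,
       cvError = mErr, path = path)
}

# balanced fold assignment, seeded
.cvFolds <- function(n, k, seed) {
  if (n < k) stop("fewer observations than folds", call. = FALSE)
  .withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}
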