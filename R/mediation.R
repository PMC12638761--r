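#' @include elasticNet.R
NULL

#' Partial correlation
#'
#' Pearson correlation of the OLS residuals of \code{x} and \code{y} on the
#' control variables, with a two-sided t test on
#' \eqn{df = n - \#controls - 2}. With no controls this reduces to the
#' ordinary Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param controls optional matrix/data.frame of control variables
#'   (e.g. age and sex).
#' @return list with \code{r}, \code{p}, \code{df}.
#' @export
partialCorrelation <- function(x, y, controls = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  nc <- if (is.null(controls)) 0L else NCOL(controls)
  if (n <= nc + 2L) stop("too few observations", call. = FALSE)
  rx <- drop(.residualize(x, controls))
  ry <- drop(.residualize(y, controls))
  if (sd(rx) < .Machine$double.eps^0.5 || sd(ry) < .Machine$double.eps^0.5) {
    stop("zero residual variance", call. = FALSE)
  }
  r <- cor(rx, ry)
  df <- n - nc - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df)
}

#' Global (single-mediator) mediation model
#'
#' Two OLS equations, \eqn{M = a X + covariates} and
#' \eqn{Y = b M + c' X + covariates}; the indirect effect is \eqn{ab} with
#' the delta-method (Sobel) standard error
#' \eqn{\sqrt{a^2 se_b^2 + b^2 se_a^2}} and, optionally, a seeded
#' percentile bootstrap confidence interval. Statistical significance of
#' the individual paths is deliberately not a precondition for running the
#' model.
#'
#' @param X independent variable (e.g. the polygenic score).
#' @param M scalar mediator (e.g. global efficiency of one band).
#' @param Y dependent variable (g).
#' @param covariates optional covariate matrix/data.frame (age, sex,
#'   PC1..PC4).
#' @param nBoot bootstrap draws for the percentile CI (0 = delta method
#'   only).
#' @param level confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list with paths \code{a}, \code{b}, \code{cPrime}, the indirect
#'   effect \code{ab}, standard errors, and \code{ci} (2-vector).
#' @export
globalMediation <- function(X, M, Y, covariates = NULL, nBoot = 0,
                            level = 0.95, seed = 1L) {
  n <- length(X)
  stopifnot(length(M) == n, length(Y) == n)
  if (sd(M) < .Machine$double.eps^0.5) {
    stop("zero-variance mediator", call. = FALSE)
  }
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  fit <- function(Xv, Mv, Yv, Cv) {
    d1 <- if (is.null(Cv)) data.frame(M = Mv, X = Xv)
          else data.frame(M = Mv, X = Xv, Cv)
    m1 <- lm(M ~ ., data = d1)
    d2 <- if (is.null(Cv)) data.frame(Y = Yv, M = Mv, X = Xv)
          else data.frame(Y = Yv, M = Mv, X = Xv, Cv)
    m2 <- lm(Y ~ ., data = d2)
    s1 <- summary(m1)$coefficients
    s2 <- summary(m2)$coefficients
    list(a = s1["X", 1], seA = s1["X", 2],
         b = s2["M", 1], seB = s2["M", 2],
         cPrime = s2["X", 1], seCPrime = s2["X", 2])
  }
  est <- fit(X, M, Y, C)
  ab <- est$a * est$b
  seAb <- sqrt(est$a^2 * est$seB^2 + est$b^2 * est$seA^2)
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- c(ab - zq * seAb, ab + zq * seAb)
  if (nBoot > 0) {
    draws <- .withSeed(seed, {
      vapply(seq_len(nBoot), function(i) {
        idx <- sample.int(n, replace = TRUE)
        Ci <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
        e <- tryCatch(fit(X[idx], M[idx], Y[idx], Ci),
                      error = function(err) NULL)
        if (is.null(e)) NA_real_ else e$a * e$b
      }, numeric(1))
    })
    ci <- unname(quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE))
  }
  c(est, list(ab = ab, seAb = seAb, ci = ci, nBoot = nBoot))
}

# soft threshold
.soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# shared-lambda single-predictor elastic net for the path-a block:
# for each mediator column m_j, fit m_j ~ x with one lambda chosen by
# pooled k-fold CV error over all columns (closed-form coefficients)
.pathA <- function(x, M, penalty) {
  n <- length(x)
  p <- ncol(M)
  alpha <- penalty$alpha
  cAll <- drop(crossprod(M, x)) / n
  aEff <- max(alpha, 1e-3)
  lamMax <- max(max(abs(cAll)) / aEff, 1e-8)
  grid <- exp(seq(log(lamMax), log(lamMax * penalty$lambdaMinRatio),
                  length.out = penalty$nLambda))
  folds <- .cvFolds(n, penalty$k, penalty$seed)
  err <- matrix(0, penalty$k, length(grid))
  for (f in seq_len(penalty$k)) {
    test <- folds == f
    xt <- x[!test]; Mt <- M[!test, , drop = FALSE]
    nt <- length(xt)
    v <- sum(xt^2) / nt
    cf <- drop(crossprod(Mt, xt)) / nt           # p vector
    # beta_{j,l} = S(c_j, lam_l * alpha) / (v + lam_l (1 - alpha))
    B <- outer(cf, grid, function(cc, ll) .soft(cc, ll * alpha)) /
      outer(rep(v, p), grid * (1 - alpha), `+`)
    for (l in seq_along(grid)) {
      R <- M[test, , drop = FALSE] - outer(x[test], B[, l])
      err[f, l] <- sum(R^2) / (sum(test) * p)
    }
  }
  mErr <- colMeans(err)
  best <- which.min(mErr)
  lam <- grid[best]
  v <- sum(x^2) / n
  a <- .soft(cAll, lam * alpha) / (v + lam * (1 - alpha))
  list(a = a, lambda = lam, cvError = mErr, grid = grid)
}

#' Exploratory mediation by regularization (xmed)
#'
#' Region-specific mediator selection between a polygenic score X and g
#' through a block of p candidate mediators M (one nodal graph metric per
#' ROI). Covariates are residualized out of X, every mediator and Y, and
#' all variables are z-scored, so the selection thresholds act on
#' standardized effects. Two elastic-net models are fitted: path a
#' (each mediator on X; p single-predictor fits sharing one lambda chosen
#' by pooled cross-validation error) and path b (Y on all mediators jointly,
#' lambda by cross-validation). A mediator is selected when
#' \eqn{|a_j| > t_{path}}, \eqn{|b_j| > t_{path}} and
#' \eqn{|a_j b_j| > t_{med}}. Because the penalty biases effects towards
#' zero, selected mediators are re-estimated without penalty: each
#' \eqn{a_j} by OLS of \eqn{M_j} on X, and all \eqn{b_j} jointly in one
#' unpenalized multiple-mediator OLS of Y on the selected mediators and X.
#'
#' @param X independent variable vector (polygenic score).
#' @param M participants x ROIs mediator matrix; column names become ROI
#'   labels.
#' @param Y dependent variable (g).
#' @param covariates optional covariate matrix/data.frame.
#' @param penalty a [penaltyConfig()]; alpha = 0.5 and k = 10 by default.
#' @param tMed threshold on |ab| (default 0.001).
#' @param tPath threshold on |a| and |b| (default 0.01).
#' @param band,metric,group provenance tags stored on the result.
#' @param jointReestimate joint (default) or one-at-a-time unpenalized
#'   re-estimation of path b.
#' @return A [MediationSelection-class].
#' @export
xmed <- function(X, M, Y, covariates = NULL, penalty = penaltyConfig(),
                 tMed = 0.001, tPath = 0.01, band = "", metric = "",
                 group = "", jointReestimate = TRUE) {
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(length(X) == n, length(Y) == n)
  if (is.null(colnames(M))) colnames(M) <- paste0("ROI", seq_len(ncol(M)))
  cc <- complete.cases(M) & is.finite(X) & is.finite(Y)
  if (!is.null(covariates)) cc <- cc & complete.cases(as.matrix(covariates))
  if (!all(cc)) {
    M <- M[cc, , drop = FALSE]; X <- X[cc]; Y <- Y[cc]
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[cc, , drop = FALSE]
    n <- nrow(M)
  }
  if (any(apply(M, 2L, sd) < .Machine$double.eps^0.5)) {
    stop("zero-variance mediator", call. = FALSE)
  }
  x <- .zscore(drop(.residualize(X, covariates)), "independent variable")
  y <- .zscore(drop(.residualize(Y, covariates)), "dependent variable")
  Mr <- .residualize(M, covariates)
  Mr <- apply(Mr, 2L, .zscore, what = "mediator")

  pa <- .pathA(x, Mr, penalty)
  fb <- elasticNet(Mr, y, penalty)
  a <- pa$a
  b <- fb$coef
  ab <- a * b
  selected <- abs(a) > tPath & abs(b) > tPath & abs(ab) > tMed

  p <- ncol(Mr)
  aRe <- bRe <- abRe <- seAbRe <- rep(NA_real_, p)
  if (any(selected)) {
    sel <- which(selected)
    seA <- rep(NA_real_, p)
    for (j in sel) {
      sm <- summary(lm(Mr[, j] ~ x))$coefficients
      aRe[j] <- sm["x", 1]; seA[j] <- sm["x", 2]
    }
    if (jointReestimate) {
      d <- data.frame(y = y, Mr[, sel, drop = FALSE], x = x)
      sm <- summary(lm(y ~ ., data = d))$coefficients
      nm <- colnames(Mr)[sel]
      bRe[sel] <- sm[nm, 1]
      seB <- rep(NA_real_, p); seB[sel] <- sm[nm, 2]
    } else {
      seB <- rep(NA_real_, p)
      for (j in sel) {
        sm <- summary(lm(y ~ Mr[, j] + x))$coefficients
        bRe[j] <- sm[2, 1]; seB[j] <- sm[2, 2]
      }
    }
    abRe <- aRe * bRe
    seAbRe <- sqrt(aRe^2 * seB^2 + bRe^2 * seA^2)
  }

  tab <- data.frame(
    roi = colnames(Mr), a = a, b = b, ab = ab, selected = selected,
    aRe = aRe, bRe = bRe, abRe = abRe, seAbRe = seAbRe,
    stringsAsFactors = FALSE
  )
  new("MediationSelection", table = tab, lambdaA = pa$lambda,
      lambdaB = fb$lambda, thresholds = c(path = tPath, med = tMed),
      band = band, metric = metric, group = group)
}

#' All band-by-metric mediation models, by age group
#'
#' Runs one [xmed()] model per band and nodal metric (5 bands x
#' {nodal efficiency, local clustering} = 10 models) for the young group
#' (age <= cutoff), the older group (age > cutoff) and the whole sample.
#'
#' @param metricTables nested list \code{metricTables[[band]][[metric]]} =
#'   participants x ROI matrix; metrics named \code{nodal_efficiency} and
#'   \code{local_clustering}.
#' @param pgs polygenic score vector.
#' @param g g factor vector.
#' @param covariates covariate data.frame containing at least \code{age}.
#' @param ageCutoff age split (default 40; the boundary age goes to young).
#' @param penalty a [penaltyConfig()].
#' @param groups subset of \code{c("young", "older", "whole")}.
#' @param ... passed to [xmed()] (thresholds etc.).
#' @return nested list \code{result[[group]][[band]][[metric]]} of
#'   [MediationSelection-class] objects.
#' @export
runBandModels <- function(metricTables, pgs, g, covariates, ageCutoff = 40,
                          penalty = penaltyConfig(),
                          groups = c("young", "older", "whole"), ...) {
  covariates <- as.data.frame(covariates)
  stopifnot("age" %in% names(covariates))
  n <- nrow(covariates)
  split <- splitCohort(covariates, cutoff = ageCutoff)
  idx <- list(young = split$young, older = split$older, whole = seq_len(n))
  cvCols <- setdiff(names(covariates), "id")
  out <- list()
  for (grp in groups) {
    rows <- idx[[grp]]
    if (length(rows) < penalty$k) {
      stop("group '", grp, "' has fewer participants than CV folds",
           call. = FALSE)
    }
    out[[grp]] <- list()
    for (band in names(metricTables)) {
      out[[grp]][[band]] <- list()
      for (metric in names(metricTables[[band]])) {
        Mmat <- metricTables[[band]][[metric]]
        out[[grp]][[band]][[metric]] <- xmed(
          X = pgs[rows], M = Mmat[rows, , drop = FALSE], Y = g[rows],
          covariates = covariates[rows, cvCols, drop = FALSE],
          penalty = penalty, band = band, metric = metric, group = grp, ...)
      }
    }
  }
  out
}
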