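#' @include graphMetrics.R
NULL

#' The fixed second-order factor structure of the cognitive battery
#'
#' Fifteen test scores load on four correlated first-order factors --
#' verbal memory (VLMT_1_5, VLMT_R_E), attention (D2_R, Stroop_2, Stroop_3,
#' TMT_A, TMT_B, DS_total, LPS_3, LPS_7), working memory (DS_f, DS_b, MWT)
#' and verbal fluency (MWT, WF_S, WF_W; the vocabulary test MWT cross-loads)
#' -- and the four factors load on a single second-order factor g. The
#' structure is fixed; exploratory re-discovery is deliberately not part of
#' the pipeline.
#'
#' @return list with elements \code{indicators} (15 names), \code{factors}
#'   (named list mapping factor name to indicator names) and
#'   \code{secondOrder} (logical).
#' @export
gFactorStructure <- function() {
  list(
    indicators = c("VLMT_1_5", "VLMT_R_E", "D2_R", "Stroop_2", "Stroop_3",
                   "TMT_A", "TMT_B", "DS_total", "LPS_3", "LPS_7",
                   "DS_f", "DS_b", "MWT", "WF_S", "WF_W"),
    factors = list(
      verbal_memory = c("VLMT_1_5", "VLMT_R_E"),
      attention = c("D2_R", "Stroop_2", "Stroop_3", "TMT_A", "TMT_B",
                    "DS_total", "LPS_3", "LPS_7"),
      working_memory = c("DS_f", "DS_b", "MWT"),
      verbal_fluency = c("MWT", "WF_S", "WF_W")
    ),
    secondOrder = TRUE
  )
}

# loading pattern matrix (indicators x factors, logical) from a structure
.loadingPattern <- function(structure) {
  ind <- structure$indicators
  fac <- names(structure$factors)
  pat <- matrix(FALSE, length(ind), length(fac), dimnames = list(ind, fac))
  for (f in fac) pat[structure$factors[[f]], f] <- TRUE
  if (any(rowSums(pat) == 0)) stop("every indicator must load on a factor")
  pat
}

#' Residualize cognitive scores for age and sex
#'
#' Regresses every score on age, sex, age x sex, age^2 and age^2 x sex
#' (quadratic age relations are common across the adult lifespan), then
#' z-standardizes the residuals (mean 0, SD 1). Participants with a missing
#' value in any score or covariate are dropped listwise first.
#'
#' @param scores numeric matrix or data.frame, participants x tests.
#' @param age,sex numeric covariate vectors (sex coded 0/1).
#' @return list with \code{residuals} (z-scored residual matrix) and
#'   \code{kept} (row indices of complete cases used).
#' @export
residualizeScores <- function(scores, age, sex) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(age), nrow(scores) == length(sex))
  keep <- which(complete.cases(scores) & is.finite(age) & is.finite(sex))
  if (length(keep) < 10L) stop("too few complete cases", call. = FALSE)
  y <- scores[keep, , drop = FALSE]
  a <- age[keep]; s <- sex[keep]
  X <- cbind(age = a, sex = s, ageSex = a * s, age2 = a^2, age2Sex = a^2 * s)
  res <- .residualize(y, X)
  res <- apply(res, 2L, function(col) .zscore(col, "residualized score"))
  list(residuals = res, kept = keep)
}

# model-implied covariance under unit latent variances
.impliedCov <- function(lambdaFree, gamma, theta, pat) {
  L <- matrix(0, nrow(pat), ncol(pat))
  L[pat] <- lambdaFree
  if (ncol(pat) > 1L) {
    Phi <- tcrossprod(gamma) + diag(1 - gamma^2, ncol(pat))
  } else {
    Phi <- matrix(1, 1, 1)
  }
  L %*% Phi %*% t(L) + diag(theta, nrow(pat))
}

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p
.mlDiscrepancy <- function(Sigma, S, logDetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logDet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  val <- logDet + tr - logDetS - nrow(S)
  if (!is.finite(val)) 1e10 else val
}

#' Fit the second-order confirmatory factor model of g
#'
#' Maximum-likelihood estimation of the factor model on a matrix of
#' residualized, z-scored test scores. Identification fixes all latent
#' variances to 1 (first-order factor disturbances are then
#' \eqn{1 - \gamma_k^2}), so all loadings are standardized. The ML
#' discrepancy \eqn{F = \log|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) -
#' \log|S| - p} is minimized by a quasi-Newton optimizer over free loadings,
#' tanh-parameterized second-order loadings and log-parameterized unique
#' variances, with up to \code{maxRestarts} random restarts when
#' convergence fails. \eqn{\chi^2 = (n-1) F_{min}}.
#'
#' Heywood tendencies (unique variances collapsing towards 0, second-order
#' loadings at the unit bound) are reported in \code{optimInfo}, never
#' silently truncated.
#'
#' @param residuals participants x indicators matrix (see
#'   [residualizeScores()]); column names must match the structure.
#' @param structure factor structure, default [gFactorStructure()]; a
#'   single-factor structure (one entry in \code{factors}) is also accepted.
#' @param maxRestarts random restarts after a failed optimization.
#' @return A [FittedGFactorModel-class].
#' @export
fitCfa <- function(residuals, structure = gFactorStructure(), maxRestarts = 5) {
  residuals <- as.matrix(residuals)
  pat <- .loadingPattern(structure)
  p <- nrow(pat); q <- ncol(pat)
  if (is.null(colnames(residuals))) {
    if (ncol(residuals) != p) stop("indicator count mismatch", call. = FALSE)
    colnames(residuals) <- rownames(pat)
  }
  Y <- residuals[, rownames(pat), drop = FALSE]
  n <- nrow(Y)
  S <- cov(Y)
  chS <- tryCatch(chol(S), error = function(e) {
    stop("sample covariance is not positive definite", call. = FALSE)
  })
  logDetS <- 2 * sum(log(diag(chS)))

  nLam <- sum(pat)
  nPar <- nLam + (if (q > 1L) q else 0L) + p
  if (n <= nPar) stop("more free parameters than observations", call. = FALSE)

  unpack <- function(par) {
    lam <- par[seq_len(nLam)]
    gamma <- if (q > 1L) tanh(par[nLam + seq_len(q)]) else numeric(0)
    theta <- exp(par[(nPar - p + 1L):nPar])
    list(lam = lam, gamma = gamma, theta = theta)
  }
  objective <- function(par) {
    u <- unpack(par)
    Sigma <- .impliedCov(u$lam, u$gamma, u$theta, pat)
    .mlDiscrepancy(Sigma, S, logDetS)
  }

  startPar <- function(jitter = 0) {
    lam0 <- rep(0.6, nLam)
    g0 <- if (q > 1L) rep(atanh(0.7), q) else numeric(0)
    th0 <- rep(log(0.5), p)
    out <- c(lam0, g0, th0)
    if (jitter > 0) out <- out + rnorm(length(out), 0, jitter)
    out
  }

  best <- NULL
  for (attempt in 0:maxRestarts) {
    par0 <- startPar(jitter = if (attempt == 0) 0 else 0.2)
    fit <- tryCatch(
      nlminb(par0, objective, control = list(iter.max = 2000, eval.max = 4000)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (!is.null(best) && best$objective < 1e9 && best$convergence == 0) break
  }
  if (is.null(best)) stop("CFA optimization failed on all restarts", call. = FALSE)

  # forward-difference gradient at the solution, reported for diagnostics
  gr <- vapply(seq_along(best$par), function(j) {
    h <- 1e-6 * max(1, abs(best$par[j]))
    pj <- best$par; pj[j] <- pj[j] + h
    (objective(pj) - best$objective) / h
  }, numeric(1))
  converged <- best$convergence == 0 && best$objective < 1e9

  u <- unpack(best$par)
  # orient: factors positive on their mean indicator, g positive overall
  L <- matrix(0, p, q, dimnames = dimnames(pat))
  L[pat] <- u$lam
  gamma <- u$gamma
  for (k in seq_len(q)) {
    if (sum(L[, k]) < 0) {
      L[, k] <- -L[, k]
      if (q > 1L) gamma[k] <- -gamma[k]
    }
  }
  if (q > 1L && sum(gamma) < 0) gamma <- -gamma
  theta <- u$theta

  Sigma <- .impliedCov(L[pat], gamma, theta, pat)
  Fmin <- .mlDiscrepancy(Sigma, S, logDetS)
  chi2 <- (n - 1) * Fmin
  df <- p * (p + 1) / 2 - nPar
  chi2B <- (n - 1) * (sum(log(diag(S))) - logDetS)
  dfB <- p * (p - 1) / 2
  fi <- c(
    list(chi2 = chi2, df = df,
         pValue = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_),
    cfaFitStatistics(chi2, df, chi2B, dfB, n),
    list(srmr = .srmr(S, Sigma), chi2Baseline = chi2B, dfBaseline = dfB)
  )

  heywood <- any(theta < 1e-3) || (q > 1L && any(abs(gamma) > 0.999))
  model <- new("FittedGFactorModel",
    loadings = L,
    secondOrder = if (q > 1L) gamma else 1,
    uniqueVars = setNames(theta, rownames(pat)),
    factorDisturbances = if (q > 1L) setNames(1 - gamma^2, colnames(pat))
                         else setNames(0, colnames(pat)),
    fitIndices = fi,
    gScores = numeric(0),
    factorScores = matrix(0, 0, q),
    impliedCov = Sigma,
    sampleCov = S,
    nObs = as.integer(n),
    converged = converged,
    optimInfo = list(objective = best$objective, gradientNorm = max(abs(gr)),
                     iterations = best$iterations, heywood = heywood,
                     message = best$message),
    structure = structure)
  model@gScores <- factorScores(model, Y)
  model@factorScores <- .firstOrderScores(model, Y)
  model
}

#' Fit statistics from chi-square values
#'
#' Standard incremental/absolute fit indices:
#' \eqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df (n-1))}},
#' \eqn{CFI = 1 - \max(\chi^2 - df, 0)/\max(\chi^2_b - df_b, \chi^2 - df, 0)},
#' \eqn{TLI = ((\chi^2_b/df_b) - (\chi^2/df)) / ((\chi^2_b/df_b) - 1)}.
#' RMSEA and TLI are undefined (NA) when df = 0.
#'
#' @param chi2,df fitted model chi-square and degrees of freedom.
#' @param chi2Baseline,dfBaseline independence (baseline) model values.
#' @param n number of observations.
#' @return list with \code{rmsea}, \code{cfi}, \code{tli}.
#' @export
cfaFitStatistics <- function(chi2, df, chi2Baseline, dfBaseline, n) {
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else NA_real_
  denom <- max(chi2Baseline - dfBaseline, chi2 - df, 0)
  cfi <- if (denom > 0) 1 - max(chi2 - df, 0) / denom else 1
  tli <- if (df > 0 && dfBaseline > 0) {
    rb <- chi2Baseline / dfBaseline
    rm <- chi2 / df
    (rb - rm) / (rb - 1)
  } else NA_real_
  list(rmsea = rmsea, cfi = cfi, tli = tli)
}

# standardized root mean squared residual, diagonal included
.srmr <- function(S, Sigma) {
  d <- sqrt(diag(S))
  std <- (S - Sigma) / outer(d, d)
  sqrt(mean(std[lower.tri(std, diag = TRUE)]^2))
}

#' Regression-method factor scores for g
#'
#' Thurstone (regression) scores for the second-order factor:
#' \eqn{\hat g = Cov(g, y)' \Sigma^{-1} y} with
#' \eqn{Cov(y, g) = \Lambda \gamma} under unit latent variances; scores are
#' then z-standardized and oriented to correlate positively with the mean
#' indicator.
#'
#' @param model a [FittedGFactorModel-class].
#' @param residuals indicator matrix to score (columns as in the structure).
#' @return numeric vector of standardized g scores.
#' @export
factorScores <- function(model, residuals) {
  stopifnot(is(model, "FittedGFactorModel"))
  Y <- as.matrix(residuals)[, rownames(model@loadings), drop = FALSE]
  Yc <- sweep(Y, 2L, colMeans(Y))
  covYg <- model@loadings %*% matrix(model@secondOrder, ncol = 1)
  wts <- solve(model@impliedCov, covYg)
  g <- drop(Yc %*% wts)
  g <- .zscore(g, "g score")
  if (cor(g, rowMeans(Yc)) < 0) g <- -g
  g
}

# regression scores for the first-order factors
.firstOrderScores <- function(model, residuals) {
  Y <- as.matrix(residuals)[, rownames(model@loadings), drop = FALSE]
  Yc <- sweep(Y, 2L, colMeans(Y))
  q <- ncol(model@loadings)
  Phi <- if (q > 1L) tcrossprod(model@secondOrder) + diag(model@factorDisturbances)
         else matrix(1, 1, 1)
  covYF <- model@loadings %*% Phi
  Yc %*% solve(model@impliedCov, covYF)
}
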