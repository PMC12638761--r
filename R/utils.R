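#' @include AllClasses.R
NULL

## internal numerical helpers

# z-standardize; errors on (near) zero variance because downstream thresholds
# act on standardized effects
.zscore <- function(x, what = "variable") {
  s <- sd(x)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    stop("zero-variance ", what, ": cannot standardize", call. = FALSE)
  }
  (x - mean(x)) / s
}

# OLS residuals of y (vector or matrix) on design X; intercept always added
.residualize <- function(y, X = NULL) {
  y <- as.matrix(y)
  if (is.null(X) || NCOL(X) == 0L) {
    return(sweep(y, 2L, colMeans(y)))
  }
  X <- cbind(1, as.matrix(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular covariate design", call. = FALSE)
  y - X %*% qr.coef(qrX, y)
}

# covariate design matrix from a covariate table (age, sex, PC1..PC4 when present)
.covariateDesign <- function(covariates,
                             columns = c("age", "sex", "PC1", "PC2", "PC3", "PC4")) {
  keep <- intersect(columns, names(covariates))
  as.matrix(covariates[, keep, drop = FALSE])
}

# deterministic sub-seed derived from a master seed; stays below 2^31
.subSeed <- function(seed, index) {
  x <- (as.double(seed) * 2654435761 + as.double(index) * 40503) %% 2147483647
  as.integer(x)
}

# symmetric matrix from an upper-triangle vector
.symFromUpper <- function(v, n, diagValue = 0) {
  m <- matrix(diagValue, n, n)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diagValue
  m
}

# participant id helper
.padIds <- function(n, prefix = "P") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}
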