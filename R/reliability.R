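#' @include mediation.R
NULL

# qualitative label for an ICC value
.iccLabel <- function(icc) {
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good" else "excellent"
}

#' ICC(3,1): two-way mixed-effects consistency reliability
#'
#' Single-measurement, consistency-form intraclass correlation for
#' test-retest data with k = 2 fixed sessions as "raters". From the two-way
#' ANOVA decomposition (subjects x sessions),
#' \eqn{ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE)} where MSR is the
#' between-subject and MSE the residual mean square. The consistency form
#' is insensitive to an additive session effect. The p value is one-sided
#' (H1: ICC > 0) from \eqn{F = MSR/MSE} with \eqn{(n-1, (n-1)(k-1))}
#' degrees of freedom.
#'
#' @param session1,session2 paired measurement vectors (same participants,
#'   same order), n >= 3.
#' @return An [IccResult-class].
#' @examples
#' icc31(c(1, 4, 5), c(2, 3, 6))
#' @export
icc31 <- function(session1, session2) {
  x <- cbind(session1, session2)
  if (any(!is.finite(x))) stop("non-finite values", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rowM <- rowMeans(x)
  colM <- colMeans(x)
  grand <- mean(x)
  ssRows <- k * sum((rowM - grand)^2)
  ssCols <- n * sum((colM - grand)^2)
  ssTot <- sum((x - grand)^2)
  ssErr <- ssTot - ssRows - ssCols
  msr <- ssRows / (n - 1)
  mse <- ssErr / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps) {
    stop("zero between-subject variance", call. = FALSE)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  new("IccResult", icc = icc, msr = msr, mse = mse, fValue = f,
      df1 = df1, df2 = df2, p = p, label = .iccLabel(icc))
}

#' Test-retest reliability map of graph metrics
#'
#' ICC(3,1) between the two recording sessions for every global metric
#' (global efficiency and clustering per band) and every nodal metric
#' (nodal efficiency and local clustering per band and ROI), plus summary
#' counts of the qualitative labels per band.
#'
#' @param metrics1,metrics2 per-session metric structures as returned by
#'   [cohortGraphMetrics()], nested per band:
#'   \code{metrics[[band]] = list(E, C, Ei, Ci)} with participants in rows.
#' @return list with \code{table} (data.frame: scope, band, roi, icc, F, p,
#'   label) and \code{summary} (label counts per band for nodal metrics).
#' @export
reliabilityMap <- function(metrics1, metrics2) {
  stopifnot(identical(names(metrics1), names(metrics2)))
  rows <- list()
  for (band in names(metrics1)) {
    m1 <- metrics1[[band]]; m2 <- metrics2[[band]]
    if (length(m1$E) != length(m2$E)) {
      stop("participant mismatch between sessions", call. = FALSE)
    }
    for (gm in c("E", "C")) {
      r <- icc31(m1[[gm]], m2[[gm]])
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "global", band = band,
        metric = if (gm == "E") "global_efficiency" else "global_clustering",
        roi = NA_character_, icc = r@icc, F = r@fValue, p = r@p,
        label = r@label, stringsAsFactors = FALSE)
    }
    for (nm in c("Ei", "Ci")) {
      lab <- colnames(m1[[nm]])
      if (is.null(lab)) lab <- paste0("ROI", seq_len(ncol(m1[[nm]])))
      for (j in seq_len(ncol(m1[[nm]]))) {
        r <- icc31(m1[[nm]][, j], m2[[nm]][, j])
        rows[[length(rows) + 1L]] <- data.frame(
          scope = "nodal", band = band,
          metric = if (nm == "Ei") "nodal_efficiency" else "local_clustering",
          roi = lab[j], icc = r@icc, F = r@fValue, p = r@p,
          label = r@label, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  nodal <- tab[tab$scope == "nodal", ]
  summ <- as.data.frame(table(band = nodal$band, label = nodal$label))
  list(table = tab, summary = summ)
}
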