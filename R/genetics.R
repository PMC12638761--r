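#' @include gfactor.R
NULL

# effect-allele frequency per SNP from a dosage matrix, NA-aware
.alleleFreq <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' SNP quality control
#'
#' Removes SNPs with minor-allele frequency below \code{mafMin}, with a
#' Hardy-Weinberg-equilibrium 1-df chi-square p value below \code{hwePMin},
#' or with missingness above \code{missMax}.
#'
#' @param genotypes participants x SNPs dosage matrix (0/1/2, NA = missing);
#'   column names are SNP ids.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param hwePMin minimum HWE p value (default 1e-6).
#' @param missMax maximum SNP missingness (default 0.02).
#' @return the filtered dosage matrix (columns dropped).
#' @export
snpQc <- function(genotypes, mafMin = 0.05, hwePMin = 1e-6, missMax = 0.02) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L) stop("need >= 2 participants", call. = FALSE)
  miss <- colMeans(is.na(genotypes))
  p <- .alleleFreq(genotypes)
  maf <- pmin(p, 1 - p)
  hweP <- apply(genotypes, 2L, .hwePValue)
  keep <- miss <= missMax & maf >= mafMin & (is.na(hweP) | hweP >= hwePMin)
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("all SNPs removed by QC", call. = FALSE)
  genotypes[, keep, drop = FALSE]
}

# 1-df chi-square HWE test from observed genotype counts
.hwePValue <- function(dos) {
  dos <- dos[!is.na(dos)]
  n <- length(dos)
  if (n < 2L) return(NA_real_)
  nAA <- sum(dos == 2); nAa <- sum(dos == 1); naa <- sum(dos == 0)
  p <- (2 * nAA + nAa) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(nAA, nAa, naa) - e)^2 / e)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Sample quality control
#'
#' Drops participants with per-sample SNP missingness above \code{missMax}
#' or a method-of-moments inbreeding coefficient
#' \eqn{F = 1 - O(het)/E(het)} beyond \code{hetLimit} in absolute value
#' (excess homozygosity or heterozygosity).
#'
#' @param genotypes participants x SNPs dosage matrix after [snpQc()].
#' @param missMax maximum per-sample missingness (default 0.02).
#' @param hetLimit limit on |F| (default 0.2).
#' @return list with \code{kept} (row indices), \code{F} and
#'   \code{missingness} per participant.
#' @export
sampleQc <- function(genotypes, missMax = 0.02, hetLimit = 0.2) {
  genotypes <- as.matrix(genotypes)
  miss <- rowMeans(is.na(genotypes))
  p <- .alleleFreq(genotypes)
  expHet <- 2 * p * (1 - p)
  het <- genotypes == 1
  Fhat <- vapply(seq_len(nrow(genotypes)), function(i) {
    ok <- !is.na(genotypes[i, ])
    eh <- sum(expHet[ok])
    if (eh <= 0) return(NA_real_)
    1 - sum(het[i, ok]) / eh
  }, numeric(1))
  kept <- which(miss <= missMax & !is.na(Fhat) & abs(Fhat) <= hetLimit)
  list(kept = kept, F = Fhat, missingness = miss)
}

#' Relatedness filtering
#'
#' Estimates pairwise relatedness (pi-hat scale) with a method-of-moments
#' genomic-relationship estimator,
#' \eqn{\hat\pi_{jk} = \sum_m (x_{jm} - 2p_m)(x_{km} - 2p_m) /
#' \sum_m 2 p_m (1 - p_m)}, on a high-quality SNP subset (HWE p > 0.02,
#' MAF > 0.2, 0\% missingness). Expected values: 1 for duplicates/identical
#' twins, 0.5 for parent-offspring, 0 for unrelated pairs. From every pair
#' above \code{pihatMax} one member is removed at random (seeded).
#'
#' @param genotypes participants x SNPs dosage matrix.
#' @param pihatMax relatedness threshold (default 0.2).
#' @param seed RNG seed for the random choice within flagged pairs.
#' @return list with \code{kept} (row indices) and \code{pihat}
#'   (participants x participants matrix).
#' @export
relatednessFilter <- function(genotypes, pihatMax = 0.2, seed = 1L) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  p <- .alleleFreq(genotypes)
  maf <- pmin(p, 1 - p)
  hweP <- apply(genotypes, 2L, .hwePValue)
  hq <- which(colSums(is.na(genotypes)) == 0 & maf > 0.2 &
              (!is.na(hweP) & hweP > 0.02))
  if (length(hq) < 10L) hq <- which(colSums(is.na(genotypes)) == 0 & maf > 0.05)
  if (length(hq) < 2L) stop("no high-quality SNPs for relatedness", call. = FALSE)
  X <- genotypes[, hq, drop = FALSE]
  pm <- .alleleFreq(X)
  Z <- sweep(X, 2L, 2 * pm)
  denom <- sum(2 * pm * (1 - pm))
  pihat <- tcrossprod(Z) / denom
  diag(pihat) <- 1
  flagged <- which(pihat > pihatMax & upper.tri(pihat), arr.ind = TRUE)
  drop <- integer(0)
  if (nrow(flagged)) {
    rng <- .withSeed(seed, runif(nrow(flagged)))
    for (r in seq_len(nrow(flagged))) {
      pair <- flagged[r, ]
      if (any(pair %in% drop)) next
      drop <- c(drop, pair[[if (rng[r] < 0.5) 1L else 2L]])
    }
  }
  list(kept = setdiff(seq_len(n), drop), pihat = pihat)
}

# evaluate expr under a temporary seed, restoring RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Principal-component ancestry outlier filter
#'
#' Computes genotype principal components (dosages mean-imputed and scaled
#' for the PCA only) and removes participants farther than \code{sdLimit}
#' standard deviations from the mean on at least one of the first
#' \code{nPcs} PCs. The first four PCs are returned as covariates for all
#' downstream models.
#'
#' @param genotypes participants x SNPs dosage matrix.
#' @param sdLimit outlier limit in SD units (default 4.5).
#' @param nPcs number of PCs screened (default 20).
#' @param nCovariatePcs number of PCs exported as covariates (default 4).
#' @return list with \code{kept} (row indices), \code{pcs} (participants x
#'   nCovariatePcs matrix, computed before exclusion) and \code{rotation}.
#' @export
pcOutlierFilter <- function(genotypes, sdLimit = 4.5, nPcs = 20,
                            nCovariatePcs = 4) {
  genotypes <- as.matrix(genotypes)
  X <- genotypes
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2L, sd)
  X <- X[, sds > 0, drop = FALSE]
  maxPcs <- min(nrow(X) - 1L, ncol(X))
  if (nPcs > maxPcs) stop("nPcs exceeds the rank of the genotype matrix",
                          call. = FALSE)
  pca <- prcomp(X, center = TRUE, scale. = TRUE, rank. = max(nPcs, nCovariatePcs))
  scores <- pca$x[, seq_len(nPcs), drop = FALSE]
  zs <- scale(scores)
  bad <- apply(abs(zs) > sdLimit, 1L, any)
  pcs <- pca$x[, seq_len(nCovariatePcs), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(nCovariatePcs))
  list(kept = which(!bad), pcs = pcs, rotation = pca$rotation)
}

# harmonize GWAS effect alleles against genotype SNP metadata:
# flip beta when the GWAS effect allele is the genotype table's other allele
.harmonizeGwas <- function(gwas, snpInfo) {
  m <- match(gwas$snp, snpInfo$snp)
  keep <- !is.na(m)
  gwas <- gwas[keep, , drop = FALSE]
  info <- snpInfo[m[keep], , drop = FALSE]
  same <- gwas$effectAllele == info$effectAllele
  flipped <- gwas$effectAllele == info$otherAllele &
             gwas$otherAllele == info$effectAllele
  usable <- same | flipped
  gwas <- gwas[usable, , drop = FALSE]
  gwas$beta[flipped[usable]] <- -gwas$beta[flipped[usable]]
  gwas
}

#' Polygenic score at a fixed p-value threshold
#'
#' Weighted allele sum \eqn{score_i = \sum_{snp: p \le t} \beta \cdot
#' dosage_i} over the SNPs shared by the genotype table and the GWAS
#' summary, after allele harmonization (beta flipped when effect/other
#' alleles are swapped). Missing dosages are imputed with twice the
#' effect-allele frequency.
#'
#' @param genotypes participants x SNPs dosage matrix with SNP column names.
#' @param gwas data.frame with columns snp, effectAllele, otherAllele, beta,
#'   p.
#' @param pThreshold include SNPs with GWAS p <= pThreshold.
#' @param snpInfo data.frame with snp, effectAllele, otherAllele for the
#'   genotype table; when NULL, GWAS alleles are taken as already aligned.
#' @return numeric score vector, one value per participant.
#' @export
computePgs <- function(genotypes, gwas, pThreshold, snpInfo = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!is.null(snpInfo)) gwas <- .harmonizeGwas(gwas, snpInfo)
  gwas <- gwas[gwas$p <= pThreshold, , drop = FALSE]
  idx <- match(gwas$snp, colnames(genotypes))
  ok <- !is.na(idx)
  if (!any(ok)) stop("no SNP passes the threshold", call. = FALSE)
  G <- genotypes[, idx[ok], drop = FALSE]
  af <- .alleleFreq(G)
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- 2 * af[j]
  }
  drop(G %*% gwas$beta[ok])
}

#' Best-fit polygenic score threshold search with permutation correction
#'
#' Evaluates the incremental \eqn{R^2} of the polygenic score over a
#' covariate-only model (covariates: age, sex, first genetic PCs) across a
#' dense grid of GWAS p-value thresholds (default 5e-5 to 1 in steps of
#' 5e-5, scores updated incrementally over p-sorted SNPs) and picks the
#' threshold with the largest increment. Because the threshold is optimized,
#' the best-fit p value is overfitted; a permutation test repeats the entire
#' search \code{bPerm} times on phenotype permutations and reports
#' \eqn{p = (1 + \#\{ \max R^2_{perm} \ge \max R^2_{obs}\}) / (B + 1)}.
#'
#' @param genotypes participants x SNPs dosage matrix.
#' @param gwas GWAS summary data.frame (snp, effectAllele, otherAllele,
#'   beta, p).
#' @param g phenotype vector (the g factor).
#' @param covariates data.frame/matrix of covariates (age, sex, PC1..PC4).
#' @param gridStep threshold grid step (default 5e-5).
#' @param bPerm number of phenotype permutations (default 1000; 0 disables
#'   the correction and \code{permutationP} is NA).
#' @param snpInfo optional allele metadata for harmonization.
#' @param seed RNG seed for the permutations.
#' @return A [PgsResult-class].
#' @export
thresholdSearch <- function(genotypes, gwas, g, covariates,
                            gridStep = 5e-5, bPerm = 1000, snpInfo = NULL,
                            seed = 1L) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  stopifnot(length(g) == n)
  if (!is.null(snpInfo)) gwas <- .harmonizeGwas(gwas, snpInfo)
  idx <- match(gwas$snp, colnames(genotypes))
  ok <- !is.na(idx)
  gwas <- gwas[ok, , drop = FALSE]
  G <- genotypes[, idx[ok], drop = FALSE]
  af <- .alleleFreq(G)
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- 2 * af[j]
  }

  X <- as.matrix(covariates)
  Xi <- cbind(1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) stop("collinear covariates", call. = FALSE)
  residOf <- function(v) v - Xi %*% qr.coef(qrX, v)

  ord <- order(gwas$p)
  beta <- gwas$beta[ord]
  pSorted <- gwas$p[ord]
  Z <- apply(G[, ord, drop = FALSE], 2L, residOf)  # covariate-residualized dosages

  # grid-snapped inclusion: a p-sorted prefix is evaluable when the next SNP
  # falls into a strictly later grid cell
  cell <- ceiling(pSorted / gridStep)
  m <- length(beta)
  lastInCell <- which(diff(c(cell, Inf)) > 0)
  thr <- pmin(cell[lastInCell] * gridStep, 1)

  # cumulative score norms ||s_t||^2 via the update
  # ||s_t||^2 = ||s_{t-1}||^2 + 2 b_t <s_{t-1}, z_t> + b_t^2 ||z_t||^2
  s <- numeric(n)
  norms2 <- numeric(m)
  acc <- 0
  for (t in seq_len(m)) {
    zt <- Z[, t] * beta[t]
    acc <- acc + 2 * sum(s * zt) + sum(zt^2)
    norms2[t] <- acc
    s <- s + zt
  }

  gResid <- residOf(matrix(g, ncol = 1))
  ssTot <- sum((g - mean(g))^2)
  r2Cov <- 1 - sum(gResid^2) / ssTot

  # cumulative inner products <s_t, g_resid> for observed + permuted phenotypes
  perms <- if (bPerm > 0) {
    .withSeed(.subSeed(seed, 977L), replicate(bPerm, sample.int(n)))
  } else NULL
  Yall <- if (bPerm > 0) {
    cbind(gResid, apply(perms, 2L, function(pp) residOf(matrix(g[pp], ncol = 1))))
  } else gResid
  Amat <- crossprod(Z, Yall) * beta            # m x (B+1)
  Cum <- apply(Amat, 2L, cumsum)               # cumulative numerators
  Cum <- matrix(Cum, nrow = m)

  yNorm2 <- colSums(Yall^2)
  ssTotPerm <- if (bPerm > 0) {
    c(ssTot, vapply(seq_len(bPerm), function(b) {
      gp <- g[perms[, b]]
      sum((gp - mean(gp))^2)
    }, numeric(1)))
  } else ssTot

  valid <- lastInCell[norms2[lastInCell] > 1e-12]
  if (!length(valid)) stop("no threshold yields a non-constant score", call. = FALSE)
  thrValid <- pmin(cell[valid] * gridStep, 1)
  # partial r^2 -> R^2 increment = partial r^2 * (1 - R^2_cov)
  r2part <- Cum[valid, , drop = FALSE]^2 /
    outer(norms2[valid], yNorm2)
  r2covAll <- 1 - yNorm2 / ssTotPerm
  r2inc <- sweep(r2part, 2L, 1 - r2covAll, `*`)

  obs <- r2inc[, 1]
  bestIdx <- which.max(obs)
  bestT <- thrValid[bestIdx]
  bestR2 <- obs[bestIdx]
  permP <- NA_real_
  if (bPerm > 0) {
    maxPerm <- apply(r2inc[, -1, drop = FALSE], 2L, max)
    permP <- (1 + sum(maxPerm >= bestR2)) / (bPerm + 1)
  }
  bestScore <- drop(G[, ord, drop = FALSE][, seq_len(valid[bestIdx]), drop = FALSE] %*%
                    beta[seq_len(valid[bestIdx])])
  new("PgsResult",
      thresholds = thrValid, r2Increment = pmax(obs, 0),
      bestThreshold = bestT, bestR2 = bestR2, bestScore = bestScore,
      permutationP = permP, nPermutations = as.integer(bPerm))
}
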