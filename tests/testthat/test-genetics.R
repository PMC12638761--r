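makeDosage <- function(n, maf, m = length(maf)) {
  G <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  colnames(G) <- sprintf("rs%04d", seq_len(m))
  G
}

test_that("SNP QC removes low-MAF, HWE-violating and high-missingness SNPs", {
  set.seed(70)
  G <- makeDosage(100, rep(0.3, 5))
  G[, 2] <- rbinom(100, 2, 0.04)            # MAF ~ 0.04
  G[, 3] <- 1L                              # all heterozygous: chi2 = n = 100
  G[1:3, 4] <- NA                           # 3% missing
  Gq <- snpQc(G)
  expect_identical(colnames(Gq), colnames(G)[c(1, 5)])
  # all-het chi-square equals n exactly
  expect_equal(unname(BrainNetMed:::.hwePValue(rep(1L, 100))),
               pchisq(100, 1, lower.tail = FALSE))
  # idempotence
  expect_identical(snpQc(Gq), Gq)
  expect_error(snpQc(matrix(rbinom(200, 2, 0.01), 100, 2)), "all SNPs")
})

test_that("sample QC flags missingness and extreme heterozygosity", {
  set.seed(71)
  G <- makeDosage(200, runif(400, 0.2, 0.5))
  Gbad <- G
  Gbad[7, ] <- NA                            # fully missing participant
  Gbad[13, ] <- ifelse(Gbad[13, ] == 1L, 2L, Gbad[13, ])  # fully homozygous
  sq <- sampleQc(Gbad)
  expect_false(7 %in% sq$kept)
  expect_false(13 %in% sq$kept)
  expect_gt(sq$F[13], 0.9)
  # a clean HWE cohort keeps (nearly) everyone
  sq2 <- sampleQc(G)
  expect_gte(length(sq2$kept) / 200, 0.99)
  expect_lt(abs(mean(sq2$F)), 0.02)
})

test_that("relatedness is ~1 for duplicates, ~0.5 for parent-offspring, ~0 otherwise", {
  set.seed(72)
  maf <- runif(1500, 0.25, 0.5)
  G <- makeDosage(60, maf)
  rel0 <- relatednessFilter(G)
  off <- rel0$pihat[upper.tri(rel0$pihat)]
  expect_lt(max(abs(off)), 0.2)
  expect_identical(rel0$kept, seq_len(60))

  Gdup <- rbind(G, G[1, ])
  reld <- relatednessFilter(Gdup, seed = 5)
  expect_gt(reld$pihat[1, 61], 0.9)
  expect_identical(length(reld$kept), 60L)
  expect_identical(sum(c(1, 61) %in% reld$kept), 1L)  # one of the pair stays

  # parent-offspring: child inherits one allele per SNP
  parent <- G[2, ]
  other <- rbinom(1500, 1, maf)
  child <- pmin(ifelse(parent >= 1, 1L, 0L) + other, 2L)
  child[parent == 2] <- 1L + other[parent == 2]
  Gpo <- rbind(G, child)
  relp <- relatednessFilter(Gpo, seed = 6)
  expect_gt(relp$pihat[2, 61], 0.35)
  expect_lt(relp$pihat[2, 61], 0.65)
})

test_that("PC outlier filtering removes ancestry outliers and exports orthonormal PCs", {
  set.seed(73)
  maf <- runif(800, 0.2, 0.5)
  G <- makeDosage(150, maf)
  pc <- pcOutlierFilter(G, nPcs = 20)
  expect_gte(length(pc$kept) / 150, 0.97)       # homogeneous: ~no removals
  R <- pc$rotation
  expect_lt(max(abs(crossprod(R) - diag(ncol(R)))), 1e-8)

  shifted <- rbinom(800, 2, pmin(maf + 0.35, 0.95))  # MAF-shifted outlier
  G2 <- rbind(G, shifted)
  pc2 <- pcOutlierFilter(G2, nPcs = 20)
  expect_false(151 %in% pc2$kept)
  expect_error(pcOutlierFilter(G[1:10, ], nPcs = 20), "rank")
})

test_that("polygenic scores are weighted allele sums with harmonized alleles", {
  G <- matrix(c(2L, 1L), 1, 2)
  colnames(G) <- c("rs1", "rs2")
  gwas <- data.frame(snp = c("rs1", "rs2"),
                     effectAllele = c("A", "A"), otherAllele = c("G", "G"),
                     beta = c(0.5, -1), p = c(0.01, 0.02))
  expect_equal(computePgs(G, gwas, 1), 0)
  expect_error(computePgs(G, gwas, 1e-5), "threshold")

  # flipping allele labels and negating beta leaves the score unchanged
  set.seed(74)
  Gn <- makeDosage(50, runif(20, 0.2, 0.5))
  info <- data.frame(snp = colnames(Gn), effectAllele = "A", otherAllele = "G")
  gw <- data.frame(snp = colnames(Gn), effectAllele = "A", otherAllele = "G",
                   beta = rnorm(20), p = runif(20))
  s1 <- computePgs(Gn, gw, 1, snpInfo = info)
  gwFlip <- gw
  flip <- c(3, 7, 11)
  gwFlip$effectAllele[flip] <- "G"; gwFlip$otherAllele[flip] <- "A"
  gwFlip$beta[flip] <- -gwFlip$beta[flip]
  s2 <- computePgs(Gn, gwFlip, 1, snpInfo = info)
  # score shifts by a dosage-reflection constant only through beta*2 terms;
  # harmonization maps beta -> -beta, dosage -> dosage, so sums agree exactly
  expect_equal(s1, s2, tolerance = 1e-12)

  # SNP order invariance
  s3 <- computePgs(Gn[, 20:1], gw, 1, snpInfo = info)
  expect_equal(s1, s3, tolerance = 1e-12)

  # missing dosages are imputed at 2*MAF
  Gm <- Gn
  Gm[1, 5] <- NA
  sM <- computePgs(Gm, gw, 1, snpInfo = info)
  af <- mean(Gm[, 5], na.rm = TRUE) / 2
  manual <- s1[1] - gw$beta[5] * Gn[1, 5] + gw$beta[5] * 2 * af
  expect_equal(sM[-1], s1[-1])
  expect_lt(abs(sM[1] - manual), 1e-10)
})

test_that("threshold search maximizes the covariate-adjusted R^2 increment", {
  set.seed(75)
  n <- 600
  maf <- runif(400, 0.1, 0.5)
  G <- makeDosage(n, maf)
  causal <- 1:40
  beta <- rnorm(400)
  p <- runif(400)
  p[causal] <- 10^runif(40, -8, -3.2)
  gwas <- data.frame(snp = colnames(G), effectAllele = "A", otherAllele = "G",
                     beta = beta, p = p)
  score <- scale(G[, causal] %*% beta[causal])[, 1]
  covs <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5),
                     PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
                     PC4 = rnorm(n))
  g <- sqrt(0.25) * score + sqrt(0.75) * rnorm(n)
  res <- thresholdSearch(G, gwas, g, covs, bPerm = 100, seed = 2)
  expect_true(validObject(res))
  expect_lte(res@bestThreshold, 1e-2)        # causal block found
  expect_true(all(res@r2Increment >= 0))
  expect_lt(res@permutationP, 0.05)
  # the increment at the best threshold matches a direct lm comparison
  sc <- computePgs(G, gwas, res@bestThreshold)
  r2 <- function(f) summary(f)$r.squared
  direct <- r2(lm(g ~ sc + age + sex + PC1 + PC2 + PC3 + PC4, data = covs)) -
            r2(lm(g ~ age + sex + PC1 + PC2 + PC3 + PC4, data = covs))
  expect_equal(res@bestR2, direct, tolerance = 1e-8)

  # no permutations: corrected p is explicitly absent
  res0 <- thresholdSearch(G, gwas, g, covs, bPerm = 0)
  expect_true(is.na(res0@permutationP))
})
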