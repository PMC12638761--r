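test_that("residualization removes the age/sex design exactly", {
  set.seed(50)
  n <- 400
  age <- runif(n, 20, 70)
  sex <- rbinom(n, 1, 0.5)
  X <- cbind(age, sex, age * sex, age^2, age^2 * sex)
  # scores orthogonal to the design by construction
  raw <- matrix(rnorm(n * 3), n, 3)
  orth <- raw - cbind(1, X) %*% qr.coef(qr(cbind(1, X)), raw)
  colnames(orth) <- c("s1", "s2", "s3")
  rs <- residualizeScores(orth, age, sex)
  expect_lt(max(abs(rs$residuals - scale(orth))), 1e-8)

  # a score that IS the design has zero residual variance
  expect_error(residualizeScores(cbind(a = 2 * age, b = rnorm(n)), age, sex),
               "zero-variance")

  # planted quadratic age effect: residuals orthogonal to age^2
  y <- 0.5 * age^2 + rnorm(n)
  rs2 <- residualizeScores(cbind(y = y, z = rnorm(n)), age, sex)
  expect_lt(abs(cor(rs2$residuals[, "y"], age^2)), 1e-10)
})

test_that("the second-order model recovers g at the default battery", {
  cfg <- cohortConfig(nParticipants = 500, nSnps = 10, nCausalSnps = 0,
                      seed = 60)
  trueG <- BrainNetMed:::.withSeed(1, rnorm(500))
  cov <- BrainNetMed:::.withSeed(2, data.frame(age = runif(500, 20, 70),
                                               sex = rbinom(500, 1, 0.5)))
  sc <- simulateTestScores(cfg, trueG, cov$age, cov$sex)
  rs <- residualizeScores(sc, cov$age, cov$sex)
  fit <- fitCfa(rs$residuals)
  expect_true(fit@converged)
  expect_gte(cor(gScores(fit), trueG[rs$kept]), 0.9)
  # factor scores recomputed on the same data match the stored ones
  expect_equal(factorScores(fit, rs$residuals), gScores(fit))
})

test_that("a saturated single-factor toy model is just-identified", {
  set.seed(61)
  n <- 800
  f <- rnorm(n)
  Y <- sapply(c(0.8, 0.7, 0.6), function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  colnames(Y) <- c("a", "b", "c")
  toy <- list(indicators = c("a", "b", "c"),
              factors = list(g = c("a", "b", "c")), secondOrder = FALSE)
  fit <- fitCfa(scale(Y), structure = toy)
  fi <- fitIndices(fit)
  expect_identical(fi$df, 0)
  expect_lt(fi$chi2, 0.01)
  expect_true(is.na(fi$rmsea))       # undefined at df = 0, reported as NA
  expect_equal(fi$cfi, 1, tolerance = 1e-4)
})

test_that("fit statistics follow their defining formulas", {
  s <- cfaFitStatistics(chi2 = 50, df = 50, chi2Baseline = 500,
                        dfBaseline = 100, n = 300)
  expect_equal(s$rmsea, 0)
  expect_equal(s$cfi, 1)
  # model as bad as the baseline: CFI = 0
  s0 <- cfaFitStatistics(chi2 = 500, df = 100, chi2Baseline = 500,
                         dfBaseline = 100, n = 300)
  expect_equal(s0$cfi, 0)
  s1 <- cfaFitStatistics(chi2 = 130, df = 80, chi2Baseline = 900,
                         dfBaseline = 105, n = 250)
  expect_equal(s1$rmsea, sqrt((130 - 80) / (80 * 249)))
  expect_equal(s1$tli, ((900 / 105) - (130 / 80)) / ((900 / 105) - 1))
})

test_that("a misspecified model fits worse than the generating model", {
  cfg <- cohortConfig(nParticipants = 1000, nSnps = 10, nCausalSnps = 0,
                      seed = 62)
  trueG <- BrainNetMed:::.withSeed(3, rnorm(1000))
  age <- BrainNetMed:::.withSeed(4, runif(1000, 20, 70))
  sex <- BrainNetMed:::.withSeed(5, rbinom(1000, 1, 0.5))
  sc <- simulateTestScores(cfg, trueG, age, sex)
  rs <- residualizeScores(sc, age, sex)
  fitTrue <- fitCfa(rs$residuals)
  noCross <- gFactorStructure()
  noCross$factors$verbal_fluency <- c("WF_S", "WF_W")  # drop the MWT cross-loading
  # 2-indicator factor stays identified through the second-order structure
  fitMis <- fitCfa(rs$residuals, structure = noCross)
  expect_gte(fitIndices(fitMis)$chi2 / fitIndices(fitMis)$df,
             fitIndices(fitTrue)$chi2 / fitIndices(fitTrue)$df)
})

test_that("g scores are stable under permutation and indicator reordering", {
  cfg <- cohortConfig(nParticipants = 400, nSnps = 10, nCausalSnps = 0,
                      seed = 63)
  trueG <- BrainNetMed:::.withSeed(6, rnorm(400))
  age <- BrainNetMed:::.withSeed(7, runif(400, 20, 70))
  sex <- BrainNetMed:::.withSeed(8, rbinom(400, 1, 0.5))
  sc <- simulateTestScores(cfg, trueG, age, sex)
  rs <- residualizeScores(sc, age, sex)
  fit <- fitCfa(rs$residuals)
  perm <- sample(nrow(rs$residuals))
  expect_equal(factorScores(fit, rs$residuals[perm, ]),
               gScores(fit)[perm], tolerance = 1e-8)
  # column order must not matter (scores defined up to sign; orientation
  # fixes the sign)
  shuf <- rs$residuals[, sample(ncol(rs$residuals)), drop = FALSE]
  fit2 <- fitCfa(shuf)
  expect_gt(abs(cor(gScores(fit2), gScores(fit))), 0.999)
})

test_that("the ML discrepancy is nonnegative and zero only at the sample covariance", {
  set.seed(64)
  S <- cov(matrix(rnorm(200 * 4), 200, 4))
  logDetS <- determinant(S)$modulus[1]
  expect_lt(abs(BrainNetMed:::.mlDiscrepancy(S, S, logDetS)), 1e-10)
  Sigma <- S + diag(0.5, 4)
  expect_gt(BrainNetMed:::.mlDiscrepancy(Sigma, S, logDetS), 0)
})
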