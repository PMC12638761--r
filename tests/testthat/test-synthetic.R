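test_that("genotypes follow Hardy-Weinberg frequencies at the configured MAF", {
  cfg <- cohortConfig(nParticipants = 10000, nSnps = 1, nCausalSnps = 0,
                      mafRange = c(0.5, 0.5), seed = 120)
  gen <- simulateGenetics(cfg)
  counts <- table(factor(gen$genotypes, levels = 0:2)) / 10000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
  expect_true(all(abs(counts - c(0.25, 0.5, 0.25)) < 3 * se))
  # no causal SNPs: the true score is identically zero
  expect_identical(gen$trueScore, numeric(10000))
})

test_that("causal SNPs carry small published p values and drive the score", {
  cfg <- cohortConfig(nParticipants = 300, nSnps = 400, nCausalSnps = 60,
                      seed = 121)
  gen <- simulateGenetics(cfg)
  causalIdx <- match(gen$causal, gen$gwas$snp)
  expect_true(all(gen$gwas$p[causalIdx] < 1e-3))
  expect_length(gen$causal, 60)
  expect_equal(sd(gen$trueScore), 1, tolerance = 1e-12)
  manual <- scale(gen$genotypes[, causalIdx] %*% gen$gwas$beta[causalIdx])[, 1]
  expect_equal(gen$trueScore, manual, tolerance = 1e-12)
  expect_error(cohortConfig(nSnps = 10, nCausalSnps = 20), "nCausalSnps")
})

test_that("identical seeds reproduce the cohort bit for bit", {
  cfg <- cohortConfig(nParticipants = 25, nSnps = 40, nCausalSnps = 10,
                      nRois = 12, mediatorRois = c(2, 5), seed = 122)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(c1@genotypes, c2@genotypes)
  expect_identical(c1@networks, c2@networks)
  expect_identical(c1@scores, c2@scores)
  expect_identical(c1@trueG, c2@trueG)
})

test_that("generated networks are valid coherence matrices", {
  cfg <- cohortConfig(nParticipants = 15, nSnps = 20, nCausalSnps = 5,
                      nRois = 18, mediatorRois = c(2, 6, 10), seed = 123)
  coh <- simulateCohort(cfg)
  for (bn in names(coh@networks)) {
    for (s in c("EC1", "EC2")) {
      arr <- coh@networks[[bn]][[s]]
      expect_true(all(arr >= 0 & arr < 1))
      for (i in 1:15) {
        m <- arr[, , i]
        expect_identical(m, t(m))
        expect_true(all(diag(m) == 0))
      }
    }
  }
})

test_that("planted nodal effects land near the configured aEffect", {
  aRe <- c()
  for (s in 1:5) {
    cfg <- cohortConfig(nParticipants = 400, nSnps = 50, nCausalSnps = 20,
                        bands = defaultBands()[2, , drop = FALSE], seed = 130 + s)
    coh <- simulateCohort(cfg)
    aRe <- c(aRe, coh@truth$aRealized)
  }
  expect_lt(abs(mean(aRe) - 0.4), 0.05)
})

test_that("the score-g variance share matches h2Pgs on average", {
  r2 <- vapply(1:30, function(s) {
    cfg <- cohortConfig(nParticipants = 1000, nSnps = 150, nCausalSnps = 50,
                        nRois = 20, mediatorRois = c(3, 7, 11, 15, 19),
                        bands = defaultBands()[2, , drop = FALSE],
                        h2Pgs = 0.04, seed = 200 + s)
    coh <- simulateCohort(cfg)
    cor(coh@trueScore, coh@trueG)^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.04), 0.02)
})

test_that("test scores degenerate correctly at boundary loadings", {
  cfg <- cohortConfig(nParticipants = 300, nSnps = 10, nCausalSnps = 0,
                      seed = 124)
  g <- BrainNetMed:::.withSeed(1, rnorm(300))
  age <- BrainNetMed:::.withSeed(2, runif(300, 20, 70))
  sex <- BrainNetMed:::.withSeed(3, rbinom(300, 1, 0.5))
  sc <- simulateTestScores(cfg, g, age, sex, loadings = 1, secondOrder = 1)
  # unit loadings, no uniqueness: every residualized score reproduces g
  # (up to the removal of g's own finite-sample covariate projection)
  rs <- residualizeScores(sc, age, sex)
  X <- cbind(age, sex, age * sex, age^2, age^2 * sex)
  gResid <- drop(BrainNetMed:::.residualize(g, X))
  for (j in 1:15) expect_gt(cor(rs$residuals[, j], gResid), 0.9999)

  # zero loadings + age nuisance: residualized scores ignore age
  scz <- simulateTestScores(cfg, g, age, sex, loadings = 0)
  rs0 <- residualizeScores(scz, age, sex)
  expect_true(all(abs(cor(rs0$residuals, age)) < 0.05))
  expect_true(all(abs(cor(scz, age)) > 0.1))   # nuisance was really there
})

test_that("a null mediation cohort plants exactly nothing", {
  cfg <- cohortConfig(nParticipants = 200, nSnps = 50, nCausalSnps = 10,
                      nRois = 15, mediatorRois = c(2, 6), aEffect = 0,
                      bEffect = 0, bands = defaultBands()[2, , drop = FALSE],
                      seed = 125)
  coh <- simulateCohort(cfg)
  expect_identical(coh@truth$bPerRoi, NA_real_)
  expect_lt(max(abs(coh@truth$aRealized)), 0.2)  # pure sampling noise
})

test_that("the time-series fast facts hold: pure shared sources cohere fully", {
  cfg <- cohortConfig(nParticipants = 1, nSnps = 10, nCausalSnps = 0,
                      nRois = 4, mediatorRois = integer(0), epochCount = 10,
                      seed = 126)
  ts <- simulateRoiTimeseries(cfg, 0, privateSd = 0, noiseSd = 0)[[1]]
  ep <- segmentEpochs(ts$EC1, cfg@sampleRate)
  for (b in seq_len(5)) {
    w <- netWeights(bandCoherence(ep, defaultBands()[b, ]))
    expect_true(all(w[upper.tri(w)] > 1 - 1e-6))
  }
})

test_that("cohorts round-trip through the plain-text writer", {
  cfg <- cohortConfig(nParticipants = 6, nSnps = 15, nCausalSnps = 4,
                      nRois = 8, mediatorRois = c(2, 5),
                      bands = defaultBands()[1:2, ], mediatorBand = "theta",
                      seed = 127)
  coh <- simulateCohort(cfg)
  dir <- file.path(tempdir(), "cohort-test")
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "covariates.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  net <- readNetworkTsv(file.path(dir, "networks",
                                  paste0("theta_EC1_", coh@covariates$id[3], ".tsv")))
  expect_equal(unname(net), unname(coh@networks$theta$EC1[, , 3]),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
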