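test_that("partial correlation reduces to Pearson and handles controls", {
  set.seed(90)
  n <- 500
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  pc <- partialCorrelation(x, y)
  expect_lt(abs(pc$r - cor(x, y)), 1e-12)
  expect_identical(pc$df, 498L)

  expect_equal(partialCorrelation(x, x + 0, controls = cbind(rnorm(n)))$r, 1)

  # x,y conditionally independent given z
  z <- rnorm(10000)
  x2 <- 0.7 * z + rnorm(10000)
  y2 <- 0.7 * z + rnorm(10000)
  pc2 <- partialCorrelation(x2, y2, controls = z)
  expect_lt(abs(pc2$r), 0.05)
  expect_gt(abs(cor(x2, y2)), 0.2)   # only the partial vanishes

  expect_error(partialCorrelation(z, 0.5 * z, controls = z), "residual variance")
})

test_that("global mediation estimates a, b, c' and the indirect effect", {
  set.seed(91)
  n <- 400
  X <- rnorm(n)
  M <- X + rnorm(n, 0, 1e-3)   # Y-noise << M-noise keeps b identifiable
  Y <- M + rnorm(n, 0, 1e-7)
  gm <- globalMediation(X, M, Y)
  expect_equal(gm$a, 1, tolerance = 1e-4)
  expect_equal(gm$b, 1, tolerance = 1e-4)
  expect_equal(gm$ab, 1, tolerance = 1e-4)
  expect_error(globalMediation(X, rep(1, n), Y), "zero-variance")

  # the API never gates on path significance: weak noisy paths still return
  Xw <- rnorm(n); Mw <- 0.01 * Xw + rnorm(n); Yw <- rnorm(n)
  gw <- globalMediation(Xw, Mw, Yw, covariates = cbind(age = rnorm(n)))
  expect_true(is.finite(gw$ab) && is.finite(gw$seAb))
})

test_that("delta-method CIs for a null indirect effect have near-nominal coverage", {
  set.seed(92)
  hits <- 0
  reps <- 500
  for (r in seq_len(reps)) {
    n <- 150
    X <- rnorm(n)
    M <- 0.4 * X + rnorm(n)      # a nonzero, b zero -> ab = 0
    Y <- 0.3 * X + rnorm(n)
    gm <- globalMediation(X, M, Y)
    if (gm$ci[1] <= 0 && gm$ci[2] >= 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.92)
})

test_that("bootstrap CIs are seeded and contain the point estimate region", {
  set.seed(93)
  n <- 200
  X <- rnorm(n)
  M <- 0.5 * X + rnorm(n)
  Y <- 0.5 * M + 0.2 * X + rnorm(n)
  g1 <- globalMediation(X, M, Y, nBoot = 200, seed = 4)
  g2 <- globalMediation(X, M, Y, nBoot = 200, seed = 4)
  expect_identical(g1$ci, g2$ci)
  expect_lt(g1$ci[1], g1$ab)
  expect_gt(g1$ci[2], g1$ab)
})

test_that("xmed rejects degenerate mediators and selects by thresholds", {
  set.seed(94)
  n <- 200
  X <- rnorm(n)
  M <- matrix(rnorm(n * 10), n, 10)
  M[, 4] <- 2                     # zero variance
  expect_error(xmed(X, M, rnorm(n)), "zero-variance")

  M <- matrix(rnorm(n * 10), n, 10)
  M[, 1] <- 0.6 * X + rnorm(n, 0, 0.6)
  Y <- 0.6 * scale(M[, 1])[, 1] + 0.2 * X + rnorm(n, 0, 0.6)
  sel <- xmed(X, M, Y, penalty = penaltyConfig(k = 5, seed = 2))
  tab <- selectionTable(sel)
  expect_true(tab$selected[1])
  expect_true(validObject(sel))
  # selection flags equal the threshold rule exactly
  expect_identical(tab$selected,
                   abs(tab$a) > 0.01 & abs(tab$b) > 0.01 & abs(tab$ab) > 0.001)
  # re-estimates exist only for selected mediators
  expect_true(all(is.na(tab$aRe[!tab$selected])))
  expect_true(all(is.finite(tab$aRe[tab$selected])))
})

test_that("selection is monotone in both thresholds", {
  set.seed(95)
  n <- 300
  X <- rnorm(n)
  M <- matrix(rnorm(n * 20), n, 20)
  for (j in 1:4) M[, j] <- 0.3 * X + rnorm(n)
  Y <- drop(scale(M[, 1:4]) %*% rep(0.2, 4)) + rnorm(n)
  base <- xmed(X, M, Y, penalty = penaltyConfig(k = 5, seed = 3))
  strictPath <- xmed(X, M, Y, penalty = penaltyConfig(k = 5, seed = 3),
                     tPath = 0.1)
  strictMed <- xmed(X, M, Y, penalty = penaltyConfig(k = 5, seed = 3),
                    tMed = 0.05)
  expect_true(all(selectedRois(strictPath) %in% selectedRois(base)))
  expect_true(all(selectedRois(strictMed) %in% selectedRois(base)))
})

test_that("duplicated mediator columns are selected together (grouping)", {
  set.seed(96)
  n <- 400
  X <- rnorm(n)
  M <- matrix(rnorm(n * 8), n, 8)
  M[, 1] <- 0.6 * X + rnorm(n, 0, 0.7)
  M[, 2] <- M[, 1] + rnorm(n, 0, 1e-6)
  Y <- drop(scale(M[, 1])) * 0.5 + rnorm(n, 0, 0.8)
  sel <- xmed(X, M, Y, penalty = penaltyConfig(k = 5, seed = 7))
  tab <- selectionTable(sel)
  expect_identical(tab$selected[1], tab$selected[2])
  expect_gt(abs(tab$b[1]), 0.01)
  expect_gt(abs(tab$b[2]), 0.01)
})

test_that("permuting the outcome kills the selection", {
  set.seed(97)
  n <- 300
  X <- rnorm(n)
  M <- matrix(rnorm(n * 30), n, 30)
  for (j in 1:3) M[, j] <- 0.5 * X + rnorm(n)
  Y <- drop(scale(M[, 1:3]) %*% rep(0.3, 3)) + 0.2 * X + rnorm(n)
  fsel <- numeric(10)
  for (r in 1:10) {
    Yp <- Y[sample(n)]
    s <- xmed(X, M, Yp, penalty = penaltyConfig(k = 5, seed = r))
    fsel[r] <- sum(selectionTable(s)$selected)
  }
  expect_lte(mean(fsel), 30 * 2 / 82 * 3)   # sparse under the null
})

test_that("re-estimation removes the shrinkage bias of selected effects", {
  set.seed(98)
  n <- 500
  trueB <- 0.4
  biasPen <- biasRe <- c()
  for (r in 1:10) {
    X <- rnorm(n)
    M <- matrix(rnorm(n * 15), n, 15)
    M[, 1] <- 0.5 * X + rnorm(n)
    Y <- trueB * scale(M[, 1])[, 1] + 0.2 * X + rnorm(n, 0, 0.8)
    s <- selectionTable(xmed(X, M, Y, penalty = penaltyConfig(k = 5, seed = r)))
    if (!s$selected[1]) next
    sdY <- 1  # Y standardized inside xmed; compare on that scale
    target <- trueB / sd(Y)
    biasPen <- c(biasPen, abs(s$b[1] - target))
    biasRe <- c(biasRe, abs(s$bRe[1] - target))
  }
  expect_gt(length(biasRe), 5)
  expect_lt(mean(biasRe), mean(biasPen))
})

test_that("runBandModels tags groups and is deterministic under a seed", {
  set.seed(99)
  n <- 120
  covs <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5),
                     PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
                     PC4 = rnorm(n))
  pgs <- rnorm(n)
  Ei <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("R", 1:12)))
  Ci <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("R", 1:12)))
  g <- rnorm(n)
  tabs <- list(theta = list(nodal_efficiency = Ei, local_clustering = Ci),
               beta = list(nodal_efficiency = Ei, local_clustering = Ci))
  pen <- penaltyConfig(k = 5, seed = 11)
  r1 <- runBandModels(tabs, pgs, g, covs, penalty = pen)
  r2 <- runBandModels(tabs, pgs, g, covs, penalty = pen)
  expect_identical(selectionTable(r1$whole$theta$nodal_efficiency),
                   selectionTable(r2$whole$theta$nodal_efficiency))
  # identical metric input across bands -> identical selections
  expect_identical(selectionTable(r1$young$theta$nodal_efficiency)$selected,
                   selectionTable(r1$young$beta$nodal_efficiency)$selected)
  expect_named(r1, c("young", "older", "whole"))
  covsYoung <- covs; covsYoung$age <- runif(n, 20, 30)
  expect_error(runBandModels(tabs, pgs, g, covsYoung, penalty = pen),
               "empty group")
  covsFew <- covs; covsFew$age <- c(rep(25, 3), runif(n - 3, 41, 70))
  expect_error(runBandModels(tabs, pgs, g, covsFew, penalty = pen),
               "fewer participants than CV folds")
})
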