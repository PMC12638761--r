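test_that("efficiency and clustering agree with brute-force oracles", {
  set.seed(101)
  for (i in 1:60) {  # the full 200-graph sweep runs in the acceptance suite
    n <- sample(4:15, 1)
    w <- randomNetwork(n, density = runif(1, 0.3, 1))
    if (all(w == 0)) next
    eff <- efficiency(w)
    ora <- efficiencyOracle(w)
    expect_lt(max(abs(eff$Ei - ora$Ei)), 1e-12)
    expect_lt(abs(eff$E - ora$E), 1e-12)
    clu <- clustering(w)
    orc <- clusteringOracle(w)
    expect_lt(max(abs(clu$Ci - orc$Ci)), 1e-12)
  }
})

test_that("closed-form graphs give the textbook metric values", {
  wK <- matrix(1, 5, 5); diag(wK) <- 0
  expect_equal(efficiency(wK)$E, 1)
  expect_equal(unname(clustering(wK)$C), 1)

  wP <- matrix(0, 3, 3); wP[1, 2] <- wP[2, 1] <- 1; wP[2, 3] <- wP[3, 2] <- 1
  eff <- efficiency(wP)
  expect_equal(eff$Ei, c(0.75, 1, 0.75))
  expect_equal(eff$E, 5 / 6)

  # two disconnected dyads: each node reaches one of three others
  wD <- matrix(0, 4, 4)
  wD[1, 2] <- wD[2, 1] <- 1; wD[3, 4] <- wD[4, 3] <- 1
  effD <- efficiency(wD)
  expect_equal(effD$Ei, rep(1 / 3, 4))
  expect_equal(effD$E, 1 / 3)

  wT <- matrix(0.5, 3, 3); diag(wT) <- 0
  expect_equal(clustering(wT)$Ci, rep(0.5, 3))

  wS <- matrix(0, 4, 4); wS[1, 2:4] <- 1; wS[2:4, 1] <- 1
  expect_equal(unname(clustering(wS)$C), 0)
})

test_that("shortest paths come from inverse weights with Dijkstra", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  d <- shortestPaths(w)
  expect_equal(d[1, 3], 2)
  wK <- matrix(1, 4, 4); diag(wK) <- 0
  expect_true(all(shortestPaths(wK)[upper.tri(wK)] == 1))
  expect_error(shortestPaths(matrix(c(0, -1, -1, 0), 2)), "negative")
})

test_that("global metrics are exact means of nodal metrics and stay in [0,1]", {
  set.seed(33)
  for (i in 1:25) {
    w <- randomNetwork(12, density = runif(1, 0.2, 1))
    g <- graphMetrics(w)
    expect_lt(abs(globalEfficiency(g) - mean(nodalEfficiency(g))), 1e-12)
    expect_lt(abs(globalClustering(g) - mean(localClustering(g))), 1e-12)
    expect_true(all(nodalEfficiency(g) >= 0 & nodalEfficiency(g) <= 1))
    expect_true(all(localClustering(g) >= 0 & localClustering(g) <= 1))
  }
})

test_that("raising one weight never lowers any nodal efficiency", {
  set.seed(7)
  w <- randomNetwork(10, density = 0.6)
  base <- efficiency(w)$Ei
  ut <- which(upper.tri(w), arr.ind = TRUE)
  for (rep in 1:100) {
    e <- ut[sample(nrow(ut), 1), ]
    w2 <- w
    bump <- min(1, w2[e[1], e[2]] + runif(1, 0.01, 0.5))
    w2[e[1], e[2]] <- w2[e[2], e[1]] <- bump
    expect_true(all(efficiency(w2)$Ei >= base - 1e-12))
  }
})

test_that("Holm pruning keeps strictly positive cohorts intact and drops null edges", {
  set.seed(9)
  nets <- array(runif(12 * 12 * 20, 0.05, 0.9), c(12, 12, 20))
  for (i in 1:20) {
    nets[, , i] <- (nets[, , i] + t(nets[, , i])) / 2
    diag(nets[, , i]) <- 0
  }
  pr <- holmPrune(nets)
  expect_identical(pr$result@nRemoved, 0L)          # real coherence: nothing removed
  expect_equal(pr$networks, nets)

  nets0 <- nets
  nets0[2, 5, ] <- nets0[5, 2, ] <- 0               # one identically-zero edge
  pr0 <- holmPrune(nets0)
  expect_identical(pr0$result@nRemoved, 1L)
  expect_false(pr0$result@keepMask[2, 5])
  expect_true(all(pr0$networks[2, 5, ] == 0))

  flat <- array(0.4, c(5, 5, 4))
  for (i in 1:4) diag(flat[, , i]) <- 0
  expect_error(holmPrune(flat[, , 1, drop = FALSE]), "2 participants")
  expect_error(holmPrune(array(0.4, c(5, 5, 4))), "variance")
})

test_that("pruning is group-level: one mask for every participant", {
  set.seed(10)
  nets <- array(abs(rnorm(8 * 8 * 15, 0, 0.1)), c(8, 8, 15))
  for (i in 1:15) { nets[, , i] <- (nets[, , i] + t(nets[, , i])) / 2; diag(nets[, , i]) <- 0 }
  pr <- holmPrune(nets, alpha = 0.01)
  zeroPattern <- apply(pr$networks, 3L, function(m) m == 0)
  expect_true(all(apply(zeroPattern, 1L, function(r) all(r) || !any(r))))
})

test_that("the 3-IQR rule removes exactly the planted outliers", {
  set.seed(12)
  n <- 60
  E <- matrix(runif(n * 5, 0.4, 0.6), n, 5)
  C <- matrix(runif(n * 5, 0.3, 0.5), n, 5)
  g <- rnorm(n)
  expect_identical(removeOutliers(matrix(0.5, n, 5), matrix(0.4, n, 5),
                                  rep(1.2, n)),
                   seq_len(n))          # all values identical: nobody removed
  g2 <- g
  g2[17] <- median(g) + 10 * IQR(g)
  expect_identical(setdiff(seq_len(n), removeOutliers(E, C, g2)), 17L)
  # four planted extremes across different variables
  E2 <- E; C2 <- C; g3 <- g
  E2[3, 2] <- median(E[, 2]) + 8 * IQR(E[, 2])
  C2[25, 4] <- median(C[, 4]) - 7 * IQR(C[, 4])
  g3[40] <- median(g) - 9 * IQR(g)
  E2[51, 1] <- median(E[, 1]) + 12 * IQR(E[, 1])
  expect_identical(setdiff(seq_len(n), removeOutliers(E2, C2, g3)),
                   c(3L, 25L, 40L, 51L))
  expect_error(removeOutliers(E[0, ], C[0, ], numeric(0)), "empty")
})
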