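# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulations so they share no code path with the
# package implementation.

# Floyd-Warshall all-pairs shortest paths on edge lengths 1/w
fwOracle <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# nodal/global efficiency from a distance matrix, by definition
efficiencyOracle <- function(w) {
  d <- fwOracle(w)
  n <- nrow(w)
  Ei <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    }
    Ei[i] <- s / (n - 1)
  }
  list(E = mean(Ei), Ei = Ei)
}

# weighted clustering with geometric-mean triangles, triple loop
clusteringOracle <- function(w) {
  n <- nrow(w)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
        }
      }
    }
    t_i <- t_i / 2
    Ci[i] <- 2 * t_i / (k * (k - 1))
  }
  list(C = mean(Ci), Ci = Ci)
}

# ICC(3,1) through explicit variance components: for k raters,
# decompose x_ij = mu + r_i + c_j + e_ij by least squares and form the
# consistency ICC from the subject and error variance estimates
iccOracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  ri <- rowMeans(x) - mu
  cj <- colMeans(x) - mu
  e <- x - mu - outer(ri, rep(1, k)) - outer(rep(1, n), cj)
  msr <- k * sum(ri^2) / (n - 1)
  mse <- sum(e^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# random symmetric weighted network with controllable density
randomNetwork <- function(n, density = 0.7, wMin = 0.05, wMax = 1) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  m <- sum(ut)
  vals <- ifelse(runif(m) < density, runif(m, wMin, wMax), 0)
  w[ut] <- vals
  w + t(w)
}

# elastic-net objective, evaluated literally
enetObjective <- function(X, y, b, lambda, alpha) {
  n <- nrow(X)
  sum((y - X %*% b)^2) / (2 * n) +
    lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
}

# small helper: standardized column (population scaling x'x/n = 1)
unitCol <- function(x) {
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}
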