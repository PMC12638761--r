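#' @include connectivity.R
NULL

# coerce list of CoherenceNetwork / matrices / 3-d array to n x n x P array
.asNetworkArray <- function(networks) {
  if (is.array(networks) && length(dim(networks)) == 3L) return(networks)
  if (is(networks, "CoherenceNetwork")) networks <- list(networks)
  if (is.list(networks)) {
    mats <- lapply(networks, function(x) {
      if (is(x, "CoherenceNetwork")) x@weights else as.matrix(x)
    })
    n <- nrow(mats[[1]])
    if (any(vapply(mats, nrow, 1L) != n) || any(vapply(mats, ncol, 1L) != n)) {
      stop("all networks must have identical shapes", call. = FALSE)
    }
    return(array(unlist(mats), dim = c(n, n, length(mats))))
  }
  stop("cannot interpret 'networks'", call. = FALSE)
}

#' Holm-Bonferroni group-level edge pruning
#'
#' Screens every edge of a cohort of networks against zero: for each
#' upper-triangle edge the participant weights are tested one-tailed against
#' \eqn{H_0: \mu \le 0} with a z statistic whose variance is the pooled
#' variance of *all* upper-triangle weights of all participants (the joint
#' variance of the whole network, not a per-edge variance), and the
#' resulting p values are Holm-Bonferroni corrected over all
#' \eqn{n(n-1)/2} edges at level \code{alpha}. Edges that fail are zeroed in
#' every participant's network, so the pruning mask is identical across the
#' group. On real coherence data all weights are strictly positive and no
#' edge is removed.
#'
#' @param networks cohort networks: an n x n x participants array, or a list
#'   of matrices / [CoherenceNetwork-class] objects of identical shape.
#' @param alpha family-wise error level (default 0.01, one-tailed).
#' @return A list with elements \code{result} (a [PruneResult-class]) and
#'   \code{networks} (the pruned n x n x participants array).
#' @examples
#' nets <- array(runif(10 * 10 * 8, 0.2, 0.8), c(10, 10, 8))
#' for (i in 1:8) { nets[,,i] <- (nets[,,i] + t(nets[,,i]))/2; diag(nets[,,i]) <- 0 }
#' pr <- holmPrune(nets)
#' pr$result
#' @export
holmPrune <- function(networks, alpha = 0.01) {
  A <- .asNetworkArray(networks)
  n <- dim(A)[1]
  P <- dim(A)[3]
  if (P < 2L) stop("pruning needs at least 2 participants", call. = FALSE)
  ut <- upper.tri(matrix(0, n, n))
  # participants x edges matrix of upper-triangle weights
  W <- t(apply(A, 3L, function(m) m[ut]))
  pooled <- var(as.vector(W))
  if (!is.finite(pooled) || pooled <= 0) {
    stop("pooled variance of edge weights is zero", call. = FALSE)
  }
  mu <- colMeans(W)
  z <- mu / sqrt(pooled / P)
  pRaw <- pnorm(z, lower.tail = FALSE)
  pAdj <- p.adjust(pRaw, method = "holm")
  keep <- pAdj <= alpha
  mask <- .symFromUpper(keep, n, diagValue = FALSE)
  storage.mode(mask) <- "logical"
  res <- new("PruneResult",
             keepMask = mask,
             edgeMean = .symFromUpper(mu, n),
             statistic = .symFromUpper(z, n),
             pRaw = .symFromUpper(pRaw, n, diagValue = 1),
             pAdjusted = .symFromUpper(pAdj, n, diagValue = 1),
             alpha = alpha,
             nRemoved = sum(!keep))
  numMask <- mask * 1
  diag(numMask) <- 0
  pruned <- array(apply(A, 3L, function(m) m * numMask), dim = dim(A))
  list(result = res, networks = pruned)
}

#' Shortest-path distance matrix of a weighted network
#'
#' Edge lengths are the inverse weights (strong coherence = short path);
#' absent edges (weight 0) have no direct connection. Distances are computed
#' with Dijkstra's algorithm from every node; unreachable pairs are
#' \code{Inf}.
#'
#' @param network a [CoherenceNetwork-class] or nonnegative symmetric matrix.
#' @return n x n matrix of shortest path lengths (0 on the diagonal).
#' @export
shortestPaths <- function(network) {
  w <- if (is(network, "CoherenceNetwork")) network@weights else as.matrix(network)
  if (any(w < 0)) stop("negative edge weight", call. = FALSE)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf  # self-loops never used
  d <- .dijkstraAll(len)
  diag(d) <- 0
  d
}

#' Global and nodal efficiency
#'
#' Nodal efficiency of node i is the average inverse shortest-path length to
#' all other nodes, \eqn{E_i = \frac{1}{n-1}\sum_{j \ne i} d_{ij}^{-1}}
#' (unreachable nodes contribute 0); global efficiency is the mean of the
#' nodal values.
#'
#' @inheritParams shortestPaths
#' @return list with elements \code{E} (global) and \code{Ei} (nodal vector).
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' efficiency(w)$E   # complete unit graph: 1
#' @export
efficiency <- function(network) {
  d <- shortestPaths(network)
  n <- nrow(d)
  if (n < 2L) stop("efficiency needs at least 2 nodes", call. = FALSE)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  Ei <- rowSums(inv) / (n - 1)
  list(E = mean(Ei), Ei = Ei)
}

#' Global and local (weighted) clustering
#'
#' Local clustering of node i divides the realized connections among its
#' neighbors by all possible ones, \eqn{C_i = 2 t_i^w / (k_i (k_i - 1))},
#' with the weighted triangle intensity in the geometric-mean (Onnela) form
#' \eqn{t_i^w = \frac{1}{2}\sum_{j,h}(w_{ij} w_{ih} w_{jh})^{1/3}}. Nodes
#' with fewer than two neighbors have \eqn{C_i = 0}. Global clustering is
#' the mean of the local coefficients. Weights must lie in [0, 1] (coherence
#' already does); set \code{normalize = TRUE} to divide by the maximum
#' weight first.
#'
#' @inheritParams shortestPaths
#' @param normalize divide weights by their maximum before cubing.
#' @return list with elements \code{C} (global), \code{Ci} (local vector),
#'   \code{k} (degrees) and \code{t} (triangle intensities).
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' clustering(w)$Ci   # all 0.5
#' @export
clustering <- function(network, normalize = FALSE) {
  w <- if (is(network, "CoherenceNetwork")) network@weights else as.matrix(network)
  if (any(w < 0)) stop("negative edge weight", call. = FALSE)
  if (max(w) > 1) {
    if (normalize) w <- w / max(w)
    else stop("weights exceed 1; use normalize = TRUE", call. = FALSE)
  }
  diag(w) <- 0
  W3 <- w^(1 / 3)
  t_i <- diag(W3 %*% W3 %*% W3) / 2
  k <- rowSums(w > 0)
  Ci <- ifelse(k < 2, 0, 2 * t_i / (k * (k - 1)))
  list(C = mean(Ci), Ci = Ci, k = k, t = t_i)
}

#' All graph metrics of one network
#'
#' @inheritParams shortestPaths
#' @return A [GraphMetrics-class].
#' @export
graphMetrics <- function(network) {
  eff <- efficiency(network)
  clu <- clustering(network)
  band <- if (is(network, "CoherenceNetwork")) network@band else "unspecified"
  session <- if (is(network, "CoherenceNetwork")) network@session else "unspecified"
  labels <- if (is(network, "CoherenceNetwork")) network@roiLabels
            else paste0("ROI", seq_along(eff$Ei))
  new("GraphMetrics",
      globalEfficiency = eff$E, nodalEfficiency = eff$Ei,
      globalClustering = clu$C, localClustering = clu$Ci,
      degree = clu$k, triangleIntensity = clu$t,
      band = band, session = session, roiLabels = labels)
}

#' Graph metrics for a cohort of networks
#'
#' @param networks n x n x participants array (or list of networks).
#' @return list with \code{E}, \code{C} (participant vectors) and \code{Ei},
#'   \code{Ci} (participants x ROI matrices).
#' @export
cohortGraphMetrics <- function(networks) {
  A <- .asNetworkArray(networks)
  P <- dim(A)[3]
  n <- dim(A)[1]
  E <- numeric(P); C <- numeric(P)
  Ei <- matrix(0, P, n); Ci <- matrix(0, P, n)
  for (i in seq_len(P)) {
    eff <- efficiency(A[, , i])
    clu <- clustering(A[, , i])
    E[i] <- eff$E; Ei[i, ] <- eff$Ei
    C[i] <- clu$C; Ci[i, ] <- clu$Ci
  }
  list(E = E, C = C, Ei = Ei, Ci = Ci)
}

#' Remove 3-IQR outliers on global metrics and g
#'
#' A participant is dropped when any of the supplied variables (global
#' efficiency per band, global clustering per band, or g) lies farther than
#' \code{iqrMult} interquartile ranges from that variable's median.
#'
#' @param eTable participants x bands matrix/data.frame of global efficiency.
#' @param cTable participants x bands matrix/data.frame of global clustering.
#' @param g numeric vector of g scores (same order).
#' @param iqrMult multiplier of the IQR (default 3).
#' @return integer vector of kept row indices.
#' @export
removeOutliers <- function(eTable, cTable, g, iqrMult = 3) {
  eTable <- as.matrix(eTable); cTable <- as.matrix(cTable)
  if (!nrow(eTable)) stop("empty input", call. = FALSE)
  stopifnot(nrow(eTable) == nrow(cTable), nrow(eTable) == length(g))
  X <- cbind(eTable, cTable, g)
  bad <- rep(FALSE, nrow(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    md <- median(v)
    iq <- IQR(v)
    bad <- bad | abs(v - md) > iqrMult * iq
  }
  which(!bad)
}
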