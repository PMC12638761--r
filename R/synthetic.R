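#' @include reliability.R
NULL

#' ROI labels for the 82-area cortical parcellation
#'
#' 41 Brodmann areas per hemisphere (areas 12-16, 34 and 48-52 have no
#' parcel in the atlas used), labelled \code{L_BA1 .. R_BA47}. For other
#' node counts generic labels are returned.
#'
#' @param n number of ROIs (default 82).
#' @return character vector of length n.
#' @export
brodmannRoiLabels <- function(n = 82) {
  if (n == 82) {
    ba <- setdiff(1:52, c(12:16, 34, 48:52))
    return(c(paste0("L_BA", ba), paste0("R_BA", ba)))
  }
  paste0("ROI", seq_len(n))
}

#' Configure a synthetic cohort
#'
#' Defaults describe the study conditions the analysis assumes: 434
#' participants aged 20-70, Hardy-Weinberg genotypes at common SNPs with a
#' sparse causal backbone explaining 4\% of g variance, 82 cortical ROIs
#' with five-band coherence networks from two eyes-closed recordings of 30
#' overlapping 8-s epochs at 200 Hz, high but imperfect session
#' reliability, and five mediator ROIs in the theta band whose connectivity
#' carries planted standardized path effects a = b = 0.4 (chosen for
#' statistical power; the effect sizes themselves are not empirically
#' known).
#'
#' @param nParticipants cohort size (default 434).
#' @param nSnps genotyped SNPs (default 2000; a desk-scale stand-in for a
#'   genome-wide panel).
#' @param nCausalSnps SNPs with true effects (default 200).
#' @param mafRange minor-allele-frequency range (default 0.05-0.5).
#' @param h2Pgs squared correlation between the true score and g
#'   (default 0.04).
#' @param mediatorRois ROI indices whose connectivity mediates (default 5
#'   spread ROIs).
#' @param aEffect,bEffect standardized planted path effects (default 0.4).
#' @param nRois nodes per network (default 82).
#' @param bands band table (default [defaultBands()]).
#' @param mediatorBand band carrying the planted effect (default "theta").
#' @param sessionReliability cross-session correlation of true edge logits
#'   in (0, 1] (default 0.85).
#' @param epochCount epochs per recording (default 30).
#' @param sampleRate Hz (default 200).
#' @param ageEffect,age2Effect,sexEffect nuisance effects added to raw test
#'   scores in SD units (defaults -0.3, -0.2, 0.2) so residualization is
#'   exercised.
#' @param edgeLogitMean,edgeLogitSd logit-normal edge model (defaults
#'   qlogis(0.3), 0.5).
#' @param roiCouplingSd logit-SD multiplier for mediator-clique edges
#'   (default 3): the planted edges get amplified variance so that a few
#'   edges can carry the whole nodal effect while all other ROIs stay null.
#' @param oscillatorSnr oscillator-to-white-noise amplitude ratio in the
#'   time-series generator (default 2).
#' @param stratified add two MAF-diverged subpopulations (default FALSE)
#'   to exercise the PC outlier filter.
#' @param seed master seed; all stages draw from deterministic sub-streams.
#' @return A validated [CohortConfig-class].
#' @export
cohortConfig <- function(nParticipants = 434, nSnps = 2000, nCausalSnps = 200,
                         mafRange = c(0.05, 0.5), h2Pgs = 0.04,
                         mediatorRois = c(5L, 18L, 33L, 47L, 66L),
                         aEffect = 0.4, bEffect = 0.4, nRois = 82,
                         bands = defaultBands(), mediatorBand = "theta",
                         sessionReliability = 0.85, epochCount = 30,
                         sampleRate = 200, ageEffect = -0.3,
                         age2Effect = -0.2, sexEffect = 0.2,
                         edgeLogitMean = qlogis(0.3), edgeLogitSd = 0.5,
                         roiCouplingSd = 3, oscillatorSnr = 2,
                         stratified = FALSE, seed = 1) {
  mediatorRois <- as.integer(mediatorRois)
  mediatorRois <- mediatorRois[mediatorRois <= nRois]
  new("CohortConfig",
      nParticipants = as.integer(nParticipants), nSnps = as.integer(nSnps),
      nCausalSnps = as.integer(nCausalSnps), mafRange = mafRange,
      h2Pgs = h2Pgs, mediatorRois = mediatorRois, aEffect = aEffect,
      bEffect = bEffect, nRois = as.integer(nRois), bands = bands,
      mediatorBand = mediatorBand, sessionReliability = sessionReliability,
      epochCount = as.integer(epochCount), sampleRate = sampleRate,
      ageEffect = ageEffect, age2Effect = age2Effect, sexEffect = sexEffect,
      edgeLogitMean = edgeLogitMean, edgeLogitSd = edgeLogitSd,
      roiCouplingSd = roiCouplingSd, oscillatorSnr = oscillatorSnr,
      stratified = stratified, seed = as.integer(seed))
}

#' Simulate genotypes, GWAS summary statistics and the true score
#'
#' SNPs are drawn independently with Hardy-Weinberg genotype frequencies
#' \eqn{(p^2, 2pq, q^2)} at MAFs uniform over the configured range. The
#' causal subset carries standard-normal effect sizes and small published p
#' values (log-uniform on 1e-8..1e-3); non-causal SNPs carry null effect
#' estimates with uniform p. The true score is the standardized weighted
#' allele sum over causal SNPs. In stratified mode the second half of the
#' cohort draws from MAF-diverged allele frequencies.
#'
#' @param config a [CohortConfig-class].
#' @return list with \code{genotypes} (n x m dosage matrix), \code{snpInfo},
#'   \code{gwas} (summary table), \code{trueScore}, \code{causal} (SNP ids).
#' @export
simulateGenetics <- function(config) {
  stopifnot(validObject(config))
  n <- config@nParticipants
  m <- config@nSnps
  .withSeed(.subSeed(config@seed, 1L), {
    maf <- runif(m, config@mafRange[1], config@mafRange[2])
    G <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    if (config@stratified) {
      half <- seq_len(n) > n / 2
      shift <- pmin(pmax(maf + runif(m, -0.15, 0.15), 0.02), 0.98)
      G[half, ] <- matrix(rbinom(sum(half) * m, 2L, rep(shift, each = sum(half))),
                          sum(half), m)
    }
    snp <- sprintf("rs%06d", seq_len(m))
    colnames(G) <- snp
    rownames(G) <- .padIds(n)
    nc <- config@nCausalSnps
    causal <- if (nc > 0) sort(sample.int(m, nc)) else integer(0)
    beta <- rnorm(m)
    p <- runif(m)
    p[causal] <- 10^runif(length(causal), -8, -3)
    trueScore <- if (nc > 0) {
      raw <- drop(G[, causal, drop = FALSE] %*% beta[causal])
      if (sd(raw) > 0) .zscore(raw) else raw * 0
    } else numeric(n)
    list(
      genotypes = G,
      snpInfo = data.frame(snp = snp, effectAllele = "A", otherAllele = "G",
                           maf = maf, stringsAsFactors = FALSE),
      gwas = data.frame(snp = snp, effectAllele = "A", otherAllele = "G",
                        beta = beta, p = p, stringsAsFactors = FALSE),
      trueScore = trueScore,
      causal = snp[causal]
    )
  })
}

# band-limited unit-variance Gaussian noise via FFT masking; one column per
# independent realization
.bandNoise <- function(nSamples, sampleRate, fLo, fHi, ncols = 1L) {
  x <- matrix(rnorm(nSamples * ncols), nSamples, ncols)
  X <- mvfft(x)
  freq <- (seq_len(nSamples) - 1) * sampleRate / nSamples
  freq <- pmin(freq, sampleRate - freq)  # two-sided
  X[freq < fLo | freq > fHi, ] <- 0
  y <- Re(mvfft(X, inverse = TRUE)) / nSamples
  s <- apply(y, 2L, sd)
  s[s == 0] <- 1
  y <- sweep(y, 2L, s, `/`)
  if (ncols == 1L) drop(y) else y
}

# independent band-limited noise for every column across ALL (disjoint)
# bands in one FFT pass: each band's bins are scaled so that the band
# contributes variance sd^2 per column
.multibandNoise <- function(nSamples, sampleRate, bands, ncols, sdPerBand) {
  x <- matrix(rnorm(nSamples * ncols), nSamples, ncols)
  X <- mvfft(x)
  freq <- (seq_len(nSamples) - 1) * sampleRate / nSamples
  freq <- pmin(freq, sampleRate - freq)
  gain <- numeric(nSamples)
  for (b in seq_len(nrow(bands))) {
    inBand <- freq >= bands$fLo[b] & freq <= bands$fHi[b]
    nb <- sum(inBand)
    if (nb > 0) gain[inBand] <- sdPerBand * sqrt(nSamples / nb)
  }
  Re(mvfft(X * gain, inverse = TRUE)) / nSamples
}

#' Simulate two-session ROI time series
#'
#' Each ROI signal is a sum of band-limited oscillators plus white noise:
#' per band, a shared source is mixed into every ROI with a
#' participant-specific coupling weight, plus a private band-limited
#' component and broadband noise. For mediator ROIs the coupling to the
#' mediator band's shared source scales linearly with the participant's
#' standardized genetic score (slope \code{aEffect}), which makes their
#' inter-ROI band coherence score-dependent. Participant coupling profiles
#' persist across the two sessions up to \code{sessionReliability} (convex
#' variance mixing with fresh session noise); sources and noise are drawn
#' fresh per session.
#'
#' Memory note: one participant's two sessions at the default configuration
#' hold ~4 M doubles; for large cohorts request participants in chunks (the
#' cohort builder streams one participant at a time).
#'
#' @param config a [CohortConfig-class].
#' @param geneticScore standardized score vector (length nParticipants).
#' @param participants indices to generate (default all).
#' @param privateSd amplitude of the private band-limited component
#'   (default 1; 0 makes coupled ROIs pure copies of the shared source).
#' @param noiseSd broadband noise amplitude; default derived from
#'   \code{oscillatorSnr}. 0 disables noise.
#' @return list indexed like \code{participants}; each element has matrices
#'   \code{EC1} and \code{EC2} (nRois x samples).
#' @export
simulateRoiTimeseries <- function(config, geneticScore,
                                  participants = seq_len(config@nParticipants),
                                  privateSd = 1, noiseSd = NULL) {
  stopifnot(validObject(config))
  bands <- config@bands
  fs <- config@sampleRate
  for (i in seq_len(nrow(bands))) .checkBand(bands[i, ], fs)
  L <- as.integer(8 * fs)
  step <- as.integer(4 * fs)
  nSamp <- (config@epochCount - 1L) * step + L
  nR <- config@nRois
  if (is.null(noiseSd)) noiseSd <- 1 / config@oscillatorSnr
  rho <- config@sessionReliability
  medBandIdx <- match(config@mediatorBand, bands$name)

  out <- vector("list", length(participants))
  for (ii in seq_along(participants)) {
    i <- participants[ii]
    out[[ii]] <- .withSeed(.subSeed(config@seed, 3000L + i), {
      # participant-level coupling profile per band x ROI, unit mean
      baseCoup <- matrix(1 + 0.2 * rnorm(nrow(bands) * nR), nrow(bands), nR)
      for (r in config@mediatorRois) {
        baseCoup[medBandIdx, r] <- 1 + config@aEffect * geneticScore[i]
      }
      sessions <- lapply(1:2, function(s) {
        coup <- sqrt(rho) * baseCoup +
          sqrt(1 - rho) * matrix(0.2 * rnorm(nrow(bands) * nR), nrow(bands), nR)
        x <- matrix(0, nR, nSamp)
        for (b in seq_len(nrow(bands))) {
          shared <- .bandNoise(nSamp, fs, bands$fLo[b], bands$fHi[b])
          x <- x + outer(coup[b, ], shared)
        }
        if (privateSd > 0) {
          x <- x + t(.multibandNoise(nSamp, fs, bands, nR, privateSd))
        }
        if (noiseSd > 0) x <- x + noiseSd * matrix(rnorm(nR * nSamp), nR, nSamp)
        x
      })
      list(EC1 = sessions[[1]], EC2 = sessions[[2]])
    })
  }
  names(out) <- .padIds(config@nParticipants)[participants]
  out
}

#' Simulate coherence networks directly (fast path)
#'
#' Bypasses the time-series stage: edge weights follow a logit-normal model
#' in (0, 1). Each participant has a latent standardized edge-logit matrix.
#' In the mediator band, the edges of the mediator clique (both endpoints
#' mediator ROIs) carry the standardized genetic score with loading q and
#' amplified logit variance (\code{roiCouplingSd}); q is chosen in closed
#' form so that each mediator ROI's nodal efficiency carries a standardized
#' genetic effect close to \code{aEffect}, while ROIs outside the clique
#' have no planted edge and stay genuinely null (which is what makes
#' false-selection rates of the mediator screen interpretable). Sessions
#' mix the participant latent with fresh noise,
#' \eqn{\sqrt{\rho}\,L_i + \sqrt{1-\rho}\,E_{is}}, giving cross-session
#' edge-logit correlation exactly \code{sessionReliability}.
#'
#' @inheritParams simulateRoiTimeseries
#' @return list \code{networks[[band]][[session]]} = nRois x nRois x
#'   participants arrays, plus attribute-free helper list element
#'   \code{latentRoiFactor} (participants x mediator ROIs, truth only).
#' @export
simulateNetworksDirect <- function(config, geneticScore) {
  stopifnot(validObject(config))
  n <- config@nParticipants
  nR <- config@nRois
  rho <- config@sessionReliability
  wU <- config@roiCouplingSd
  labels <- brodmannRoiLabels(nR)
  utMask <- upper.tri(matrix(0, nR, nR))
  eIdx <- which(utMask, arr.ind = TRUE)   # edge list, upper-triangle order
  nEdge <- nrow(eIdx)
  med <- config@mediatorRois
  nets <- list()
  uMed <- NULL
  .withSeed(.subSeed(config@seed, 2L), {
    for (b in seq_len(nrow(config@bands))) {
      bn <- config@bands$name[b]
      isMedBand <- identical(bn, config@mediatorBand)
      # participant latent per edge (columns = participants)
      L <- matrix(rnorm(nEdge * n), nEdge, n)
      ampVec <- rep(1, nEdge)
      if (isMedBand && length(med)) {
        if (length(med) > 1L) {
          clique <- which(eIdx[, 1] %in% med & eIdx[, 2] %in% med)
          nPlanted <- length(med) - 1L
        } else {
          # a single mediator has no clique: plant on its incident edges
          clique <- which(eIdx[, 1] == med | eIdx[, 2] == med)
          nPlanted <- nR - 1L
        }
        # planted edges carry the score directly and get amplified logit
        # variance so that a mediator's few clique edges (of its nR-1) can
        # move its nodal efficiency by a standardized aEffect; .cliqueLoad
        q <- .cliqueLoad(config@aEffect, nPlanted, nR, wU, rho)
        L[clique, ] <- q * matrix(geneticScore, length(clique), n, byrow = TRUE) +
          sqrt(1 - q^2) * L[clique, , drop = FALSE]
        ampVec[clique] <- wU
        uMed <- t(L[clique, , drop = FALSE])
      }
      arrs <- lapply(1:2, function(s) {
        Es <- matrix(rnorm(nEdge * n), nEdge, n)
        lat <- sqrt(rho) * L + sqrt(1 - rho) * Es
        W <- plogis(config@edgeLogitMean + config@edgeLogitSd * ampVec * lat)
        arr <- array(0, c(nR, nR, n), dimnames = list(labels, labels, NULL))
        m <- matrix(0, nR, nR)
        for (i in seq_len(n)) {
          m[utMask] <- W[, i]
          arr[, , i] <- m + t(m)
        }
        arr
      })
      nets[[bn]] <- list(EC1 = arrs[[1]], EC2 = arrs[[2]])
    }
  })
  attr(nets, "latentRoiFactor") <- uMed
  nets
}

#' Simulate the 15-score cognitive battery
#'
#' First-order factors are \eqn{F_k = \gamma_k g + \sqrt{1-\gamma_k^2} d_k};
#' indicators are \eqn{y = \lambda F + \sqrt{1-\lambda^2} u} (with the
#' vocabulary test splitting its loading over working memory and verbal
#' fluency), then age, age^2 and sex nuisance effects are added so that the
#' residualization stage has something to remove.
#'
#' @param config a [CohortConfig-class].
#' @param trueG latent g vector (standardized).
#' @param age,sex covariate vectors.
#' @param loadings optional length-15 named vector of first-order loadings
#'   (defaults spread over 0.4-0.8).
#' @param secondOrder optional length-4 vector of factor-on-g loadings
#'   (defaults 0.8, 0.7, 0.75, 0.65).
#' @return participants x 15 score matrix (columns named as in
#'   [gFactorStructure()]).
#' @export
simulateTestScores <- function(config, trueG, age, sex,
                               loadings = NULL, secondOrder = NULL) {
  stopifnot(validObject(config))
  n <- length(trueG)
  struct <- gFactorStructure()
  pat <- .loadingPattern(struct)
  defaultLam <- setNames(
    c(0.80, 0.75, 0.70, 0.65, 0.68, 0.60, 0.64, 0.72, 0.58, 0.55,
      0.78, 0.74, 0.50, 0.78, 0.75),
    struct$indicators)
  lam <- if (is.null(loadings)) defaultLam else setNames(rep(loadings, length.out = 15), struct$indicators)
  gam <- if (is.null(secondOrder)) c(0.90, 0.85, 0.88, 0.82) else rep(secondOrder, length.out = 4)
  .withSeed(.subSeed(config@seed, 4L), {
    Fs <- sapply(seq_len(4), function(k) {
      gam[k] * trueG + sqrt(max(0, 1 - gam[k]^2)) * rnorm(n)
    })
    Y <- matrix(0, n, 15, dimnames = list(NULL, struct$indicators))
    for (j in seq_len(15)) {
      facs <- which(pat[j, ])
      if (length(facs) == 1L) {
        signal <- lam[j] * Fs[, facs]
        uVar <- max(0, 1 - lam[j]^2)
      } else {
        # cross-loading indicator: split the loading over its factors
        lsplit <- lam[j] / sqrt(length(facs))
        signal <- drop(Fs[, facs] %*% rep(lsplit, length(facs)))
        uVar <- max(0, 1 - var(signal))
      }
      Y[, j] <- signal + sqrt(uVar) * rnorm(n)
    }
    za <- .zscore(age)
    za2 <- .zscore(age^2)
    nuisance <- config@ageEffect * za + config@age2Effect * za2 +
      config@sexEffect * sex
    sweep(Y, 1L, nuisance, `+`)
  })
}

# score loading required on each mediator-clique edge logit so that a
# mediator ROI's nodal efficiency carries a standardized effect close to
# `target`: a mediator has k-1 clique edges (amplified logit SD `amp`) among
# its nR-1 incident edges, sessions attenuate the participant-level signal
# by 2*rho/(1+rho); first-order linearization of the efficiency metric
.cliqueLoad <- function(target, nPlanted, nR, amp, rho) {
  sessAtten <- sqrt(2 * rho / (1 + rho))  # session-mean signal share
  # 0.92: first-order correction for the logistic squashing and the
  # shortest-path nonlinearity, which attenuate the linearized effect
  q <- target * sqrt(nPlanted * amp^2 + (nR - 1 - nPlanted)) /
    (nPlanted * amp * sessAtten * 0.92)
  min(q, 0.98)
}

# build g from score + mediated network effect using empirical moments:
# g = c*score + bEffect * z(sum_r std(metric_r)) + e -- bEffect is the
# standardized effect of the mediator composite (the planted ROIs' summed
# standardized metrics); c and Var(e) are chosen so that Var(g) = 1 and
# cor(score, g)^2 = h2Pgs. The implied per-ROI regression coefficient is
# bEffect / sd(composite), recorded in the truth as bPerRoi.
.composeG <- function(config, score, mediatorMetric, seed) {
  n <- length(score)
  compositeSd <- NA_real_
  if (length(config@mediatorRois) && config@bEffect != 0) {
    Mstd <- apply(mediatorMetric, 2L, .zscore, what = "mediator metric")
    comp <- rowSums(Mstd)
    compositeSd <- sd(comp)
    B <- config@bEffect * (comp - mean(comp)) / compositeSd
  } else {
    B <- numeric(n)
  }
  s <- if (sd(score) > 0) score else rnorm(n)  # degenerate no-genetics case
  s <- .zscore(s)
  betaSB <- cov(s, B)
  cDir <- sqrt(config@h2Pgs) - betaSB
  varE <- 1 - cDir^2 - var(B) - 2 * cDir * betaSB
  if (varE <= 0) {
    stop("planted effects leave no residual g variance; reduce h2Pgs/bEffect",
         call. = FALSE)
  }
  e <- .withSeed(seed, rnorm(n, 0, sqrt(varE)))
  g <- cDir * s + B + e
  list(g = g, cDirect = cDir, varE = varE, compositeSd = compositeSd)
}

#' Simulate a complete cohort
#'
#' Runs every generator stage under one master seed: covariates, genetics,
#' networks (either the logit-normal direct model or the full band-limited
#' oscillator time series passed through [coherenceNetworks()]), the latent
#' g composed of a direct genetic effect plus the planted mediated network
#' effect, and the cognitive battery. The \code{truth} slot records what
#' was planted; no analysis function reads it.
#'
#' @param config a [CohortConfig-class].
#' @param method \code{"direct"} (default; logit-normal edges) or
#'   \code{"timeseries"} (oscillator signals, segmented and passed through
#'   the spectral-coherence estimator; slower).
#' @return A [SyntheticCohort-class].
#' @export
simulateCohort <- function(config, method = c("direct", "timeseries")) {
  method <- match.arg(method)
  stopifnot(validObject(config))
  n <- config@nParticipants
  covariates <- .withSeed(.subSeed(config@seed, 0L), {
    data.frame(
      id = .padIds(n),
      age = runif(n, 20, 70),
      sex = rbinom(n, 1L, 0.5),
      PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n), PC4 = rnorm(n),
      stringsAsFactors = FALSE
    )
  })
  gen <- simulateGenetics(config)

  if (method == "direct") {
    networks <- simulateNetworksDirect(config, gen$trueScore)
  } else {
    labels <- brodmannRoiLabels(config@nRois)
    networks <- list()
    for (bn in config@bands$name) {
      networks[[bn]] <- list(
        EC1 = array(0, c(config@nRois, config@nRois, n),
                    dimnames = list(labels, labels, NULL)),
        EC2 = array(0, c(config@nRois, config@nRois, n),
                    dimnames = list(labels, labels, NULL)))
    }
    for (i in seq_len(n)) {
      ts <- simulateRoiTimeseries(config, gen$trueScore, participants = i)[[1]]
      for (s in c("EC1", "EC2")) {
        ep <- segmentEpochs(ts[[s]], config@sampleRate, roiLabels = labels)
        ns <- coherenceNetworks(ep, config@bands)
        for (bn in config@bands$name) {
          networks[[bn]][[s]][, , i] <- ns[[bn]]@weights
        }
      }
    }
  }

  # mediator metric: nodal efficiency of session-averaged mediator-band nets
  med <- config@mediatorRois
  bandNets <- networks[[config@mediatorBand]]
  meanNets <- (bandNets$EC1 + bandNets$EC2) / 2
  if (length(med)) {
    metric <- matrix(0, n, length(med))
    for (i in seq_len(n)) {
      metric[i, ] <- efficiency(meanNets[, , i])$Ei[med]
    }
  } else {
    metric <- matrix(0, n, 0)
  }
  gc <- .composeG(config, gen$trueScore, metric, .subSeed(config@seed, 5L))
  scores <- simulateTestScores(config, gc$g, covariates$age, covariates$sex)

  aRealized <- if (length(med) && sd(gen$trueScore) > 0) {
    apply(metric, 2L, function(mcol) cor(gen$trueScore, mcol))
  } else numeric(0)

  new("SyntheticCohort",
      covariates = covariates,
      genotypes = gen$genotypes,
      snpInfo = gen$snpInfo,
      gwas = gen$gwas,
      trueScore = gen$trueScore,
      networks = networks,
      scores = scores,
      trueG = gc$g,
      truth = list(
        causalSnps = gen$causal,
        mediatorRois = med,
        mediatorBand = config@mediatorBand,
        aEffect = config@aEffect,
        bEffect = config@bEffect,
        bPerRoi = if (is.na(gc$compositeSd)) NA_real_
                  else config@bEffect / gc$compositeSd,
        aRealized = aRealized,
        cDirect = gc$cDirect,
        h2Pgs = config@h2Pgs,
        method = method
      ),
      config = config)
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes covariates.tsv, scores.tsv, genotypes.tsv, gwas.tsv, truth.json
#' and one labelled square TSV per network under
#' \code{networks/<band>_<session>_<participant>.tsv}.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(cohort@covariates, "covariates.tsv")
  wt(data.frame(id = cohort@covariates$id, cohort@scores), "scores.tsv")
  geno <- data.frame(id = cohort@covariates$id, cohort@genotypes,
                     check.names = FALSE)
  wt(geno, "genotypes.tsv")
  wt(cohort@gwas, "gwas.tsv")
  ndir <- file.path(dir, "networks")
  dir.create(ndir, showWarnings = FALSE)
  ids <- cohort@covariates$id
  for (bn in names(cohort@networks)) {
    for (s in names(cohort@networks[[bn]])) {
      arr <- cohort@networks[[bn]][[s]]
      for (i in seq_len(dim(arr)[3])) {
        writeNetworkTsv(arr[, , i],
                        file.path(ndir, paste0(bn, "_", s, "_", ids[i], ".tsv")))
      }
    }
  }
  jsonlite::write_json(cohort@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
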