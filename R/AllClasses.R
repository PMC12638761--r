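#' @include AllGenerics.R
NULL

## ------------------------------------------------------------------ ##
## CoherenceNetwork                                                    ##
## ------------------------------------------------------------------ ##

#' Weighted coherence network
#'
#' A symmetric, nonnegative ROI-by-ROI matrix of spectral-coherence weights
#' for one frequency band and one recording session. Weights lie in [0, 1];
#' the diagonal is stored as 0 and never used by any graph metric.
#'
#' @slot weights symmetric numeric matrix of coherence weights in [0, 1].
#' @slot band band name (e.g. \code{"theta"}).
#' @slot session session tag (\code{"EC1"}, \code{"EC2"} or \code{"mean"}).
#' @slot roiLabels character vector of ROI labels, one per node.
#'
#' @seealso [coherenceNetwork()], [bandCoherence()], [graphMetrics()]
#' @export
setClass("CoherenceNetwork",
  representation(
    weights = "matrix",
    band = "character",
    session = "character",
    roiLabels = "character"
  )
)

setValidity("CoherenceNetwork", function(object) {
  w <- object@weights
  msg <- character()
  if (!is.numeric(w) || nrow(w) != ncol(w)) {
    msg <- c(msg, "'weights' must be a square numeric matrix")
  } else {
    if (length(object@roiLabels) != nrow(w)) {
      msg <- c(msg, "length of 'roiLabels' must equal the matrix dimension")
    }
    if (any(!is.finite(w))) msg <- c(msg, "'weights' must be finite")
    else {
      if (max(abs(w - t(w))) > 1e-8) msg <- c(msg, "'weights' must be symmetric")
      if (min(w) < 0 || max(w) > 1) msg <- c(msg, "'weights' must lie in [0, 1]")
      if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be stored as 0")
    }
  }
  if (length(object@band) != 1L) msg <- c(msg, "'band' must be a single string")
  if (length(object@session) != 1L) msg <- c(msg, "'session' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CoherenceNetwork
#'
#' @param weights square symmetric numeric matrix with entries in [0, 1].
#'   The diagonal is forced to 0; small asymmetries (< 1e-8) are symmetrized.
#' @param band band name.
#' @param session session tag.
#' @param roiLabels optional ROI labels; defaults to \code{ROI1..ROIn}.
#' @return A [CoherenceNetwork-class] object.
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' net <- coherenceNetwork(w, band = "theta", session = "EC1")
#' globalEfficiency(graphMetrics(net))
#' @export
coherenceNetwork <- function(weights, band = "unspecified",
                             session = "unspecified", roiLabels = NULL) {
  weights <- as.matrix(weights)
  dimnames(weights) <- NULL
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(roiLabels)) roiLabels <- paste0("ROI", seq_len(nrow(weights)))
  new("CoherenceNetwork", weights = weights, band = as.character(band),
      session = as.character(session), roiLabels = as.character(roiLabels))
}

#' @rdname accessors
#' @export
setMethod("netWeights", "CoherenceNetwork", function(x, ...) x@weights)

#' @rdname accessors
#' @export
setMethod("roiLabels", "CoherenceNetwork", function(x, ...) x@roiLabels)

#' @rdname accessors
#' @export
setMethod("bandName", "CoherenceNetwork", function(x, ...) x@band)

#' @rdname accessors
#' @export
setMethod("sessionTag", "CoherenceNetwork", function(x, ...) x@session)

setMethod("show", "CoherenceNetwork", function(object) {
  n <- nrow(object@weights)
  off <- object@weights[upper.tri(object@weights)]
  cat("CoherenceNetwork:", n, "ROIs, band =", object@band,
      ", session =", object@session, "\n")
  cat(sprintf("  weights: mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
})

## ------------------------------------------------------------------ ##
## GraphMetrics                                                        ##
## ------------------------------------------------------------------ ##

#' Graph metrics of a weighted network
#'
#' Holds global and nodal efficiency, global and local (weighted, geometric
#' triangle form) clustering, degree, and the weighted triangle intensity of
#' one network. Global values are exactly the means of the nodal vectors.
#'
#' @slot globalEfficiency mean of nodal efficiencies.
#' @slot nodalEfficiency per-node average inverse shortest-path length.
#' @slot globalClustering mean of local clustering coefficients.
#' @slot localClustering per-node weighted clustering coefficient.
#' @slot degree per-node count of nonzero edges.
#' @slot triangleIntensity per-node weighted triangle intensity.
#' @slot band,session,roiLabels provenance copied from the input network.
#' @seealso [graphMetrics()]
#' @export
setClass("GraphMetrics",
  representation(
    globalEfficiency = "numeric",
    nodalEfficiency = "numeric",
    globalClustering = "numeric",
    localClustering = "numeric",
    degree = "numeric",
    triangleIntensity = "numeric",
    band = "character",
    session = "character",
    roiLabels = "character"
  )
)

setValidity("GraphMetrics", function(object) {
  n <- length(object@nodalEfficiency)
  msg <- character()
  if (length(object@localClustering) != n || length(object@degree) != n) {
    msg <- c(msg, "nodal vectors must have equal length")
  }
  if (abs(object@globalEfficiency - mean(object@nodalEfficiency)) > 1e-10) {
    msg <- c(msg, "global efficiency must equal mean nodal efficiency")
  }
  if (abs(object@globalClustering - mean(object@localClustering)) > 1e-10) {
    msg <- c(msg, "global clustering must equal mean local clustering")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("globalEfficiency", "GraphMetrics", function(x, ...) x@globalEfficiency)

#' @rdname accessors
#' @export
setMethod("nodalEfficiency", "GraphMetrics", function(x, ...) {
  setNames(x@nodalEfficiency, x@roiLabels)
})

#' @rdname accessors
#' @export
setMethod("globalClustering", "GraphMetrics", function(x, ...) x@globalClustering)

#' @rdname accessors
#' @export
setMethod("localClustering", "GraphMetrics", function(x, ...) {
  setNames(x@localClustering, x@roiLabels)
})

#' @rdname accessors
#' @export
setMethod("nodeDegree", "GraphMetrics", function(x, ...) {
  setNames(x@degree, x@roiLabels)
})

setMethod("show", "GraphMetrics", function(object) {
  cat("GraphMetrics:", length(object@nodalEfficiency), "nodes, band =",
      object@band, ", session =", object@session, "\n")
  cat(sprintf("  E = %.4f  C = %.4f\n",
              object@globalEfficiency, object@globalClustering))
})

## ------------------------------------------------------------------ ##
## PruneResult                                                         ##
## ------------------------------------------------------------------ ##

#' Result of Holm-Bonferroni group-level edge pruning
#'
#' @slot keepMask symmetric logical matrix; TRUE where the edge is retained.
#' @slot edgeMean per-edge mean weight across participants (matrix).
#' @slot statistic per-edge one-tailed z statistic (matrix).
#' @slot pRaw,pAdjusted raw and Holm-adjusted one-tailed p values (matrices).
#' @slot alpha family-wise error level used.
#' @slot nRemoved number of upper-triangle edges removed.
#' @seealso [holmPrune()]
#' @export
setClass("PruneResult",
  representation(
    keepMask = "matrix",
    edgeMean = "matrix",
    statistic = "matrix",
    pRaw = "matrix",
    pAdjusted = "matrix",
    alpha = "numeric",
    nRemoved = "integer"
  )
)

setMethod("show", "PruneResult", function(object) {
  m <- sum(upper.tri(object@keepMask))
  cat("PruneResult: Holm-Bonferroni pruning at alpha =", object@alpha, "\n")
  cat("  ", object@nRemoved, "of", m, "edges removed\n")
})

## ------------------------------------------------------------------ ##
## FittedGFactorModel                                                  ##
## ------------------------------------------------------------------ ##

#' Fitted second-order g factor model
#'
#' Maximum-likelihood second-order confirmatory factor model: 15 indicators
#' load on 4 correlated first-order factors (verbal memory, attention,
#' working memory, verbal fluency; the vocabulary test cross-loads on working
#' memory and verbal fluency), and the 4 factors load on a single
#' second-order general factor g. Latent variances are fixed to 1 so all
#' loadings are standardized.
#'
#' @slot loadings 15 x 4 matrix of first-order standardized loadings.
#' @slot secondOrder length-4 vector of factor-on-g loadings.
#' @slot uniqueVars indicator unique variances.
#' @slot factorDisturbances first-order factor disturbance variances
#'   (1 - secondOrder^2 under the unit-variance identification).
#' @slot fitIndices list: chi2, df, pValue, rmsea, srmr, cfi, tli plus the
#'   baseline model chi2/df.
#' @slot gScores standardized regression-method factor scores for g.
#' @slot factorScores n x 4 matrix of first-order factor scores.
#' @slot impliedCov,sampleCov model-implied and sample covariance matrices.
#' @slot nObs number of complete observations used.
#' @slot converged logical; optimizer convergence.
#' @slot optimInfo list with objective value, gradient norm, restarts.
#' @slot structure the [gFactorStructure()] list used.
#' @seealso [fitCfa()], [factorScores()]
#' @export
setClass("FittedGFactorModel",
  representation(
    loadings = "matrix",
    secondOrder = "numeric",
    uniqueVars = "numeric",
    factorDisturbances = "numeric",
    fitIndices = "list",
    gScores = "numeric",
    factorScores = "matrix",
    impliedCov = "matrix",
    sampleCov = "matrix",
    nObs = "integer",
    converged = "logical",
    optimInfo = "list",
    structure = "list"
  )
)

#' @rdname accessors
#' @export
setMethod("gScores", "FittedGFactorModel", function(x, ...) x@gScores)

#' @rdname accessors
#' @export
setMethod("fitIndices", "FittedGFactorModel", function(x, ...) x@fitIndices)

setMethod("show", "FittedGFactorModel", function(object) {
  fi <- object@fitIndices
  cat("FittedGFactorModel: second-order CFA,", nrow(object@loadings),
      "indicators,", length(object@secondOrder), "first-order factors\n")
  cat(sprintf("  chi2(%d) = %.3f, RMSEA = %.3f, SRMR = %.3f, CFI = %.3f, TLI = %.3f\n",
              fi$df, fi$chi2, fi$rmsea, fi$srmr, fi$cfi, fi$tli))
  cat("  second-order loadings:",
      paste(sprintf("%.2f", object@secondOrder), collapse = ", "), "\n")
})

## ------------------------------------------------------------------ ##
## PgsResult                                                           ##
## ------------------------------------------------------------------ ##

#' Best-fit polygenic score search result
#'
#' @slot thresholds evaluated GWAS p-value thresholds.
#' @slot r2Increment incremental R^2 of the score over the covariate-only
#'   model at each threshold.
#' @slot bestThreshold threshold with the largest R^2 increment.
#' @slot bestR2 R^2 increment at the best threshold.
#' @slot bestScore the best-fit score vector (one value per participant).
#' @slot permutationP permutation-corrected p for the best fit, or NA when
#'   no permutations were run.
#' @slot nPermutations number of phenotype permutations used.
#' @seealso [thresholdSearch()], [computePgs()]
#' @export
setClass("PgsResult",
  representation(
    thresholds = "numeric",
    r2Increment = "numeric",
    bestThreshold = "numeric",
    bestR2 = "numeric",
    bestScore = "numeric",
    permutationP = "numeric",
    nPermutations = "integer"
  )
)

setValidity("PgsResult", function(object) {
  msg <- character()
  if (length(object@thresholds) != length(object@r2Increment)) {
    msg <- c(msg, "thresholds and r2Increment must align")
  }
  if (length(object@r2Increment) && any(object@r2Increment < -1e-12)) {
    msg <- c(msg, "R^2 increments cannot be negative")
  }
  if (!is.na(object@permutationP) &&
      (object@permutationP <= 0 || object@permutationP > 1)) {
    msg <- c(msg, "permutationP must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PgsResult", function(object) {
  cat("PgsResult:", length(object@thresholds), "thresholds searched\n")
  cat(sprintf("  best threshold = %g, R^2 increment = %.4f\n",
              object@bestThreshold, object@bestR2))
  if (!is.na(object@permutationP)) {
    cat(sprintf("  permutation-corrected p = %.4g (%d permutations)\n",
                object@permutationP, object@nPermutations))
  }
})

## ------------------------------------------------------------------ ##
## MediationSelection                                                  ##
## ------------------------------------------------------------------ ##

#' Region-specific exploratory mediation selection
#'
#' Per-ROI elastic-net path estimates (a: score to mediator; b: mediator to
#' g), their product, the selection flag, and unpenalized re-estimates for
#' selected mediators.
#'
#' @slot table data.frame with columns roi, a, b, ab, selected, aRe, bRe,
#'   abRe, seAbRe.
#' @slot lambdaA,lambdaB cross-validated penalty weights for the two paths.
#' @slot thresholds named vector with elements \code{path} (on |a|, |b|) and
#'   \code{med} (on |ab|).
#' @slot band,metric,group provenance tags.
#' @seealso [xmed()], [runBandModels()]
#' @export
setClass("MediationSelection",
  representation(
    table = "data.frame",
    lambdaA = "numeric",
    lambdaB = "numeric",
    thresholds = "numeric",
    band = "character",
    metric = "character",
    group = "character"
  )
)

setValidity("MediationSelection", function(object) {
  need <- c("roi", "a", "b", "ab", "selected", "aRe", "bRe", "abRe", "seAbRe")
  if (!all(need %in% names(object@table))) {
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  }
  tab <- object@table
  tp <- object@thresholds[["path"]]
  tm <- object@thresholds[["med"]]
  ok <- abs(tab$a) > tp & abs(tab$b) > tp & abs(tab$ab) > tm
  if (!identical(as.logical(ok), as.logical(tab$selected))) {
    return("selection flags inconsistent with thresholds")
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("selectionTable", "MediationSelection", function(x, ...) x@table)

#' @rdname accessors
#' @export
setMethod("selectedRois", "MediationSelection", function(x, ...) {
  x@table$roi[x@table$selected]
})

setMethod("show", "MediationSelection", function(object) {
  cat("MediationSelection:", sum(object@table$selected), "of",
      nrow(object@table), "ROIs selected")
  if (nzchar(object@band)) cat(" [", object@group, "/", object@band, "/",
                               object@metric, "]", sep = "")
  cat("\n")
  cat(sprintf("  lambda_a = %.4g, lambda_b = %.4g\n",
              object@lambdaA, object@lambdaB))
})

## ------------------------------------------------------------------ ##
## IccResult                                                           ##
## ------------------------------------------------------------------ ##

#' ICC(3,1) test-retest reliability result
#'
#' Two-way mixed-effects, consistency, single-measurement intraclass
#' correlation, with the usual qualitative labels (poor < 0.5, moderate
#' < 0.75, good < 0.9, excellent otherwise).
#'
#' @slot icc ICC(3,1) value.
#' @slot msr between-subject mean square.
#' @slot mse residual mean square.
#' @slot fValue MSR / MSE.
#' @slot df1,df2 F degrees of freedom.
#' @slot p one-sided p value for ICC > 0.
#' @slot label qualitative reliability label.
#' @seealso [icc31()], [reliabilityMap()]
#' @export
setClass("IccResult",
  representation(
    icc = "numeric",
    msr = "numeric",
    mse = "numeric",
    fValue = "numeric",
    df1 = "numeric",
    df2 = "numeric",
    p = "numeric",
    label = "character"
  )
)

setValidity("IccResult", function(object) {
  msg <- character()
  if (object@icc > 1 + 1e-12) msg <- c(msg, "ICC cannot exceed 1")
  if (object@fValue < 0) msg <- c(msg, "F must be nonnegative")
  lbl <- if (object@icc < 0.5) "poor" else if (object@icc < 0.75) "moderate"
         else if (object@icc < 0.9) "good" else "excellent"
  if (!identical(lbl, object@label)) msg <- c(msg, "label inconsistent with ICC")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("iccValue", "IccResult", function(x, ...) x@icc)

setMethod("show", "IccResult", function(object) {
  cat(sprintf("IccResult: ICC(3,1) = %.3f (%s), F(%g, %g) = %.2f, p = %.3g\n",
              object@icc, object@label, object@df1, object@df2,
              object@fValue, object@p))
})

## ------------------------------------------------------------------ ##
## SyntheticCohort                                                     ##
## ------------------------------------------------------------------ ##

#' Synthetic cohort with planted effects
#'
#' One seeded draw from the generative model the analysis assumes:
#' Hardy-Weinberg genotypes with a sparse true-effect GWAS, two-session
#' coherence networks whose mediator-ROI edges shift with the true genetic
#' score, cognitive test scores loading on four first-order factors under a
#' second-order g, and age/sex/genetic-PC covariates. The \code{truth} slot
#' records planted effects for recovery testing only; analysis functions
#' never read it.
#'
#' @slot covariates data.frame: id, age, sex, PC1..PC4.
#' @slot genotypes participants x SNPs dosage matrix (0/1/2, NA allowed).
#' @slot snpInfo data.frame: snp, effectAllele, otherAllele, maf.
#' @slot gwas data.frame: snp, effectAllele, otherAllele, beta, p.
#' @slot trueScore standardized true polygenic score (truth; analysis uses
#'   scores recomputed from \code{genotypes} + \code{gwas}).
#' @slot networks nested list networks[[band]][[session]] = ROI x ROI x
#'   participant array of coherence weights.
#' @slot scores participants x 15 cognitive score matrix.
#' @slot trueG latent general-intelligence vector (truth).
#' @slot truth list of planted parameters (causal SNP ids, mediator ROIs,
#'   realized path-a/path-b effects, scaling constants).
#' @slot config the [CohortConfig-class] used.
#' @seealso [simulateCohort()]
#' @export
setClass("SyntheticCohort",
  representation(
    covariates = "data.frame",
    genotypes = "matrix",
    snpInfo = "data.frame",
    gwas = "data.frame",
    trueScore = "numeric",
    networks = "list",
    scores = "matrix",
    trueG = "numeric",
    truth = "list",
    config = "ANY"
  )
)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@covariates), "participants,",
      ncol(object@genotypes), "SNPs,", length(object@networks), "bands\n")
  cat("  mediator ROIs:",
      paste(object@truth$mediatorRois, collapse = ", "), "\n")
})

## ------------------------------------------------------------------ ##
## CohortConfig                                                        ##
## ------------------------------------------------------------------ ##

#' Synthetic cohort configuration
#'
#' Parameters of the generative model; see [cohortConfig()] for defaults and
#' units.
#'
#' @slot nParticipants,nSnps,nCausalSnps counts.
#' @slot mafRange length-2 minor-allele-frequency range in (0, 1).
#' @slot h2Pgs proportion of g variance explained by the true score.
#' @slot mediatorRois ROI indices whose connectivity mediates.
#' @slot aEffect,bEffect standardized planted path effects.
#' @slot nRois number of ROIs (82 = 41 Brodmann areas per hemisphere).
#' @slot bands band definition data.frame (name, fLo, fHi).
#' @slot mediatorBand band carrying the planted effect.
#' @slot sessionReliability cross-session correlation of true edge logits.
#' @slot epochCount target number of 8-s epochs per recording.
#' @slot sampleRate sampling rate in Hz.
#' @slot ageEffect,age2Effect,sexEffect nuisance effects on raw test scores.
#' @slot edgeLogitMean,edgeLogitSd logit-normal edge weight model.
#' @slot roiCouplingSd,oscillatorSnr time-series generator knobs.
#' @slot stratified logical; add two MAF-diverged subpopulations.
#' @slot seed master RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    nParticipants = "integer",
    nSnps = "integer",
    nCausalSnps = "integer",
    mafRange = "numeric",
    h2Pgs = "numeric",
    mediatorRois = "integer",
    aEffect = "numeric",
    bEffect = "numeric",
    nRois = "integer",
    bands = "data.frame",
    mediatorBand = "character",
    sessionReliability = "numeric",
    epochCount = "integer",
    sampleRate = "numeric",
    ageEffect = "numeric",
    age2Effect = "numeric",
    sexEffect = "numeric",
    edgeLogitMean = "numeric",
    edgeLogitSd = "numeric",
    roiCouplingSd = "numeric",
    oscillatorSnr = "numeric",
    stratified = "logical",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be positive")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be positive")
  if (object@nCausalSnps < 0L || object@nCausalSnps > object@nSnps) {
    msg <- c(msg, "need 0 <= nCausalSnps <= nSnps")
  }
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange >= 1) || object@mafRange[1] > object@mafRange[2]) {
    msg <- c(msg, "mafRange must be an increasing pair inside (0, 1)")
  }
  if (object@h2Pgs <= 0 || object@h2Pgs >= 1) {
    msg <- c(msg, "h2Pgs must lie in (0, 1)")
  }
  if (length(object@mediatorRois) &&
      (min(object@mediatorRois) < 1L || max(object@mediatorRois) > object@nRois)) {
    msg <- c(msg, "mediatorRois must lie in [1, nRois]")
  }
  if (object@sessionReliability <= 0 || object@sessionReliability > 1) {
    msg <- c(msg, "sessionReliability must lie in (0, 1]")
  }
  nyq <- object@sampleRate / 2
  if (any(object@bands$fLo <= 0) || any(object@bands$fHi >= nyq) ||
      any(object@bands$fLo > object@bands$fHi)) {
    msg <- c(msg, "bands must satisfy 0 < fLo <= fHi < Nyquist")
  }
  if (!object@mediatorBand %in% object@bands$name) {
    msg <- c(msg, "mediatorBand must be one of the configured bands")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nParticipants, "participants,", object@nSnps,
      "SNPs (", object@nCausalSnps, "causal),", object@nRois, "ROIs\n")
  cat(sprintf("  h2Pgs = %.3f, a = %.2f, b = %.2f on %d mediator ROIs (%s band)\n",
              object@h2Pgs, object@aEffect, object@bEffect,
              length(object@mediatorRois), object@mediatorBand))
  cat(sprintf("  session reliability = %.2f, seed = %d\n",
              object@sessionReliability, object@seed))
})
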