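#' @include io.R
NULL

#' Split a cohort at an age cutoff
#'
#' Young = age <= cutoff, older = age > cutoff by default (the boundary age
#' is assigned to the young group; configurable because both conventions
#' appear in age-stratified lifespan samples).
#'
#' @param covariates data.frame with an \code{age} column.
#' @param cutoff age cutoff in years (default 40).
#' @param boundaryToYoung put participants exactly at the cutoff into the
#'   young group (default TRUE).
#' @return list with integer index vectors \code{young} and \code{older}.
#' @export
splitCohort <- function(covariates, cutoff = 40, boundaryToYoung = TRUE) {
  age <- covariates$age
  if (is.null(age)) stop("covariates must contain 'age'", call. = FALSE)
  young <- if (boundaryToYoung) which(age <= cutoff) else which(age < cutoff)
  older <- setdiff(seq_along(age), young)
  if (!length(young) || !length(older)) {
    stop("age split produces an empty group", call. = FALSE)
  }
  list(young = young, older = sort(older))
}

# run one stage with an informative error prefix
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# CohortConfig -> plain list for the manifest
.configToList <- function(config) {
  sn <- slotNames(class(config))
  out <- lapply(sn, function(s) {
    v <- slot(config, s)
    if (is.data.frame(v)) as.list(v) else v
  })
  names(out) <- sn
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage in analysis order: cohort simulation; genotype,
#' sample, relatedness and PC-outlier QC; session averaging and
#' Holm-Bonferroni pruning of the coherence networks; graph metrics;
#' residualization and the second-order g model; 3-IQR outlier removal;
#' best-fit polygenic scoring with permutation correction; partial
#' correlations and global mediation; the ten band-by-metric exploratory
#' mediation models per age group; and ICC(3,1) reliability of all metrics
#' across the two sessions. All outputs are plain-text tables plus a JSON
#' manifest recording the configuration, seeds, per-stage counts and md5
#' hashes of every written file; a rerun with the same configuration is
#' bit-identical.
#'
#' @param config a [CohortConfig-class].
#' @param outDir output directory.
#' @param netMethod cohort network generation, \code{"direct"} or
#'   \code{"timeseries"} (see [simulateCohort()]).
#' @param pruneAlpha Holm-Bonferroni pruning level (default 0.01).
#' @param penalty a [penaltyConfig()] for the mediation models.
#' @param bPerm polygenic-score permutations (default 200 at pipeline
#'   scale; configurable up to the canonical 10,000).
#' @param ageCutoff age-group split (default 40).
#' @param iqrMult outlier rule multiplier (default 3).
#' @param groups mediation groups to run (default young/older/whole).
#' @param mediationMetrics which nodal metrics feed the mediation stage.
#' @return invisible list with all in-memory results (cohort, qc, metrics,
#'   gModel, pgs, mediation, reliability, manifest).
#' @export
runPipeline <- function(config, outDir, netMethod = c("direct", "timeseries"),
                        pruneAlpha = 0.01, penalty = penaltyConfig(),
                        bPerm = 200, ageCutoff = 40, iqrMult = 3,
                        groups = c("young", "older", "whole"),
                        mediationMetrics = c("nodal_efficiency",
                                             "local_clustering")) {
  netMethod <- match.arg(netMethod)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  cohort <- .stage("simulate", simulateCohort(config, method = netMethod))
  n0 <- nrow(cohort@covariates)

  ## genetics QC
  qc <- .stage("genetics_qc", {
    geno <- snpQc(cohort@genotypes)
    sq <- sampleQc(geno)
    keep <- sq$kept
    rel <- relatednessFilter(geno[keep, , drop = FALSE],
                             seed = .subSeed(config@seed, 11L))
    keep <- keep[rel$kept]
    pc <- pcOutlierFilter(geno[keep, , drop = FALSE],
                          nPcs = min(20L, length(keep) - 1L,
                                     ncol(geno)))
    keep <- keep[pc$kept]
    pcs <- pc$pcs[pc$kept, , drop = FALSE]
    list(genotypes = geno[keep, , drop = FALSE], kept = keep, pcs = pcs)
  })
  keep <- qc$kept

  covariates <- cohort@covariates[keep, , drop = FALSE]
  covariates[, paste0("PC", 1:4)] <- qc$pcs

  ## networks: session mean, group pruning, metrics
  nets <- .stage("networks", {
    out <- list()
    for (bn in names(cohort@networks)) {
      b <- cohort@networks[[bn]]
      ec1 <- b$EC1[, , keep, drop = FALSE]
      ec2 <- b$EC2[, , keep, drop = FALSE]
      mean2 <- (ec1 + ec2) / 2
      pr <- holmPrune(mean2, alpha = pruneAlpha)
      mask <- pr$result@keepMask * 1
      applyMask <- function(arr) {
        array(apply(arr, 3L, function(m) m * mask), dim = dim(arr),
              dimnames = dimnames(arr))
      }
      out[[bn]] <- list(prune = pr$result, mean = pr$networks,
                        EC1 = applyMask(ec1), EC2 = applyMask(ec2))
    }
    out
  })

  metrics <- .stage("graph_metrics", {
    lab <- brodmannRoiLabels(config@nRois)
    lapply(nets, function(b) {
      m <- cohortGraphMetrics(b$mean)
      colnames(m$Ei) <- colnames(m$Ci) <- lab
      m
    })
  })

  ## g factor
  gModel <- .stage("gfactor", {
    rs <- residualizeScores(cohort@scores[keep, , drop = FALSE],
                            covariates$age, covariates$sex)
    fitCfa(rs$residuals)
  })
  g <- gScores(gModel)

  ## outliers on global metrics and g
  out3iqr <- .stage("outliers", {
    eTab <- sapply(metrics, `[[`, "E")
    cTab <- sapply(metrics, `[[`, "C")
    removeOutliers(eTab, cTab, g, iqrMult = iqrMult)
  })
  keep2 <- out3iqr
  covariates <- covariates[keep2, , drop = FALSE]
  g <- g[keep2]
  metrics <- lapply(metrics, function(m) {
    list(E = m$E[keep2], C = m$C[keep2],
         Ei = m$Ei[keep2, , drop = FALSE], Ci = m$Ci[keep2, , drop = FALSE])
  })

  ## polygenic score
  pgs <- .stage("pgs", {
    thresholdSearch(qc$genotypes[keep2, , drop = FALSE], cohort@gwas, g,
                    covariates[, c("age", "sex", paste0("PC", 1:4))],
                    bPerm = bPerm, snpInfo = cohort@snpInfo,
                    seed = .subSeed(config@seed, 13L))
  })
  score <- .zscore(pgs@bestScore)

  ## partial correlations and global mediation (whole sample)
  globalModels <- .stage("global_mediation", {
    res <- list()
    for (bn in names(metrics)) {
      for (gm in c("E", "C")) {
        key <- paste0(bn, "_", gm)
        res[[key]] <- list(
          partial = partialCorrelation(score, g,
                                       covariates[, c("age", "sex")]),
          mediation = globalMediation(score, metrics[[bn]][[gm]], g,
                                      covariates[, c("age", "sex",
                                                     paste0("PC", 1:4))])
        )
      }
    }
    res
  })

  ## region-specific mediation
  mediation <- .stage("mediation", {
    tabs <- lapply(metrics, function(m) {
      list(nodal_efficiency = m$Ei, local_clustering = m$Ci)[mediationMetrics]
    })
    runBandModels(tabs, score, g,
                  covariates[, c("age", "sex", paste0("PC", 1:4))],
                  ageCutoff = ageCutoff, penalty = penalty, groups = groups)
  })

  ## reliability across sessions (metrics on the group-pruned mask)
  reliability <- .stage("reliability", {
    lab <- brodmannRoiLabels(config@nRois)
    perSession <- function(sess) {
      lapply(nets, function(b) {
        m <- cohortGraphMetrics(b[[sess]][, , keep2, drop = FALSE])
        colnames(m$Ei) <- colnames(m$Ci) <- lab
        m
      })
    }
    reliabilityMap(perSession("EC1"), perSession("EC2"))
  })

  ## outputs + manifest
  files <- .stage("write", {
    wt <- function(x, f) {
      write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f
    }
    ids <- covariates$id
    f1 <- wt(covariates, "covariates.tsv")
    f2 <- wt(data.frame(id = ids, g = g), "g.tsv")
    f3 <- wt(data.frame(id = ids, score = score), "pgs.tsv")
    f4 <- wt(.tidyMetrics(metrics, ids), "metrics.tsv")
    f5 <- wt(reliability$table, "reliability.tsv")
    medFiles <- character(0)
    for (grp in names(mediation)) {
      for (bn in names(mediation[[grp]])) {
        for (mm in names(mediation[[grp]][[bn]])) {
          f <- paste0("mediation_", grp, "_", bn, "_", mm, ".tsv")
          medFiles <- c(medFiles, wt(selectionTable(mediation[[grp]][[bn]][[mm]]), f))
        }
      }
    }
    pgsReport <- list(
      bestThreshold = pgs@bestThreshold, bestR2 = pgs@bestR2,
      permutationP = pgs@permutationP, nPermutations = pgs@nPermutations,
      thresholds = pgs@thresholds, r2Increment = pgs@r2Increment)
    jsonlite::write_json(pgsReport, file.path(outDir, "pgs_report.json"),
                         auto_unbox = TRUE, digits = NA)
    c(f1, f2, f3, f4, f5, medFiles, "pgs_report.json")
  })

  manifest <- .stage("manifest", {
    mf <- list(
      package = "BrainNetMed",
      version = as.character(utils::packageVersion("BrainNetMed")),
      seed = config@seed,
      netMethod = netMethod,
      config = .configToList(config),
      counts = list(
        simulated = n0,
        afterGeneticsQc = length(keep),
        afterOutliers = length(keep2),
        snpsAfterQc = ncol(qc$genotypes),
        young = sum(covariates$age <= ageCutoff),
        older = sum(covariates$age > ageCutoff)
      ),
      prunedEdges = vapply(nets, function(b) b$prune@nRemoved, integer(1)),
      files = as.list(tools::md5sum(file.path(outDir, files)))
    )
    names(mf$files) <- files
    jsonlite::write_json(mf, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mf
  })

  invisible(list(cohort = cohort, qc = qc, networks = nets, metrics = metrics,
                 gModel = gModel, g = g, pgs = pgs,
                 globalModels = globalModels, mediation = mediation,
                 reliability = reliability, covariates = covariates,
                 manifest = manifest))
}
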