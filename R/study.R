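## End-to-end replicate study on synthetic data: the package's summary
## experiment comparing set-level, gene-level and randomized-control
## representations by LOOCV accuracy, and set families by within-set
## correlation.

#' Run a replicated set-level vs gene-level comparison on synthetic data
#'
#' For each replicate, draws a fresh genome + two-class expression series
#' from the generator, builds the COPR and REG families, and computes
#' leave-one-out SVM accuracies for five representations: COPR and REG
#' set-level features (mean aggregation), the gene-level union baseline
#' (for COPR this is every gene), and the two randomized-control
#' counterparts. It also records mean within-set correlations for COPR,
#' REG and unconstrained random gene pairs.
#'
#' @param nReplicates number of independent simulated datasets.
#' @param config a \linkS4class{SimulationConfig} describing the study
#'   conditions.
#' @param seed master seed; each replicate derives its own seed from it.
#' @param corIter correlation pairs sampled per family per replicate.
#' @param classifier configuration from \code{\link{svmConfig}}.
#' @return A list of two matrices (replicates in rows): \code{accuracy}
#'   with columns \code{copr}, \code{reg}, \code{geneLevel},
#'   \code{coprRandom}, \code{regRandom}; and \code{correlation} with
#'   columns \code{copr}, \code{reg}, \code{random}.
#' @examples
#' \donttest{
#' st <- runComparisonStudy(2, simulationConfig(nOperons = 60, nTFs = 8,
#'                                              targetsPerTFRange = c(2, 8),
#'                                              nAffectedTFs = 3), seed = 1)
#' colMeans(st$accuracy)
#' }
#' @export
runComparisonStudy <- function(nReplicates = 50, config = simulationConfig(),
                               seed = 1L, corIter = 300L,
                               classifier = svmConfig()) {
  one <- function(i) {
    s <- as.integer(seed) + 7919L * i
    sim <- simulateStudy(config, seed = s)
    lab <- sampleLabels(sim$expr)
    copr <- buildCOPR(sim$annotation)
    reg <- buildREG(sim$annotation)
    acc <- c(
      copr = loocvAccuracy(aggregateSets(sim$expr, copr), lab, classifier),
      reg = loocvAccuracy(aggregateSets(sim$expr, reg), lab, classifier),
      geneLevel = loocvAccuracy(geneLevelUnion(sim$expr, copr), lab,
                                classifier),
      coprRandom = loocvAccuracy(
        aggregateSets(sim$expr, randomizeFamily(copr, seed = s + 2L)), lab,
        classifier),
      regRandom = loocvAccuracy(
        aggregateSets(sim$expr, randomizeFamily(reg, seed = s + 3L)), lab,
        classifier))
    cors <- c(
      copr = mean(sampleWithinFamily(copr, sim$expr, corIter,
                                     seed = s + 4L)$r),
      reg = mean(sampleWithinFamily(reg, sim$expr, corIter,
                                    seed = s + 5L)$r),
      random = mean(sampleRandomPairs(sim$expr, corIter, seed = s + 6L)$r))
    list(acc = acc, cors = cors)
  }
  res <- lapply(seq_len(nReplicates), one)
  list(accuracy = do.call(rbind, lapply(res, `[[`, "acc")),
       correlation = do.call(rbind, lapply(res, `[[`, "cors")))
}
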