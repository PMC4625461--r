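## Seeded synthetic genome + expression generator. Emulates the statistical
## assumptions the set-level method exploits: operons with internal
## promoters (suffix TUs) inducing always-co-transcribed chunks, a TF
## network with roles, and class-structured expression in which gene
## expression sums signed latent TF activities plus chunk-shared and
## per-gene noise.

## Operon sizes follow a truncated geometric-family law on [lo, hi] whose
## exponential weight is solved so the mean matches the target: with the
## E. coli-like default mean of 1.7 most operons are single-gene while
## sizes up to 16 remain possible.
drawOperonSizes <- function(n, lo, hi, meanTarget) {
  if (lo == hi) return(rep(lo, n))
  sizes <- lo:hi
  meanAt <- function(lq) {
    w <- exp(lq * (sizes - lo) - max(lq * (sizes - lo), 0))
    sum(sizes * w) / sum(w)
  }
  if (meanTarget <= lo) return(rep(lo, n))
  if (meanTarget >= hi) return(rep(hi, n))
  lq <- stats::uniroot(function(x) meanAt(x) - meanTarget, c(-6, 6))$root
  w <- exp(lq * (sizes - lo) - max(lq * (sizes - lo), 0))
  sample(sizes, n, replace = TRUE, prob = w)
}

#' Simulate a genome annotation with ground truth
#'
#' Draws operons with sizes from a truncated geometric-family law matching
#' the configured mean (uniform draws fall out as the special case where
#' the target mean is the range midpoint). Every operon
#' has its full-length TU; each internal inter-gene boundary carries, with
#' probability \code{pInternalPromoter}, an internal promoter spawning a
#' suffix TU (starting at the boundary and running to the operon end) —
#' the prokaryotic mechanism that makes chunk structure non-trivial. TFs
#' are genes drawn from the universe; each targets a number of
#' transcription units (default) or genes drawn without replacement, with
#' a regulatory role drawn per target from \code{roleProbs}. Gene-level
#' interactions are merged with the same rules as the network parser.
#'
#' The returned ground truth records the chunk partition implied by the
#' promoter placements, each gene's regulator key, and the affected-TF
#' list, enabling oracle tests of the builders.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer seed (default: the config's seed).
#' @return A list with elements \code{annotation}
#'   (\linkS4class{GenomeAnnotation}) and \code{truth} (list with
#'   \code{chunks}, \code{chunkOf}, \code{regulatorKeys},
#'   \code{affectedTFs}, \code{tfs}).
#' @export
simulateAnnotation <- function(config, seed = config@seed) {
  withSeed(seed, {
    sizes <- drawOperonSizes(config@nOperons, config@operonSizeRange[1],
                             config@operonSizeRange[2],
                             config@operonSizeMean)
    nGenes <- sum(sizes)
    geneIds <- sprintf("g%05d", seq_len(nGenes))
    opIds <- sprintf("op%04d", seq_len(config@nOperons))
    operons <- split(geneIds, rep(seq_len(config@nOperons), sizes))
    names(operons) <- opIds

    tus <- list(); tuOperon <- character()
    chunkOf <- character(nGenes); names(chunkOf) <- geneIds
    chunks <- list()
    for (o in seq_len(config@nOperons)) {
      genes <- operons[[o]]
      n <- length(genes)
      id <- paste0(opIds[o], ".t1")
      tus[[id]] <- genes
      tuOperon[id] <- opIds[o]
      promoterAt <- if (n > 1L)
        which(runif(n - 1L) < config@pInternalPromoter) else integer()
      k <- 1L
      for (b in promoterAt) {          # suffix TU starting after boundary b
        k <- k + 1L
        id <- paste0(opIds[o], ".t", k)
        tus[[id]] <- genes[(b + 1L):n]
        tuOperon[id] <- opIds[o]
      }
      chunkId <- cumsum(c(1L, as.integer(seq_len(max(n - 1L, 0L)) %in%
                                           promoterAt)))
      for (cix in unique(chunkId)) {
        nm <- paste0(opIds[o], ".", cix)
        chunks[[nm]] <- genes[chunkId == cix]
        chunkOf[genes[chunkId == cix]] <- nm
      }
    }

    tfs <- sample(geneIds, config@nTFs)
    units <- if (config@targetUnits == "tu") tus else
      as.list(stats::setNames(geneIds, geneIds))
    lo <- config@targetsPerTFRange[1]; hi <- config@targetsPerTFRange[2]
    if (hi > length(units))
      stop("config requests up to ", hi, " targets but only ",
           length(units), " ", config@targetUnits, "(s) exist")
    rows <- vector("list", config@nTFs)
    for (t in seq_len(config@nTFs)) {
      k <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
      hit <- sample(length(units), k)
      # a TF has one characteristic role; individual targets deviate rarely
      role <- rep(sample(ROLE_LEVELS, 1L,
                         prob = config@roleProbs[ROLE_LEVELS]), k)
      dev <- runif(k) < config@pRoleDeviation
      if (any(dev))
        role[dev] <- sample(ROLE_LEVELS, sum(dev), replace = TRUE,
                            prob = config@roleProbs[ROLE_LEVELS])
      rows[[t]] <- data.frame(
        tf = tfs[t],
        target = unlist(units[hit], use.names = FALSE),
        role = rep(role, lengths(units[hit])),
        stringsAsFactors = FALSE)
    }
    net <- mergeInteractions(do.call(rbind, rows))

    affected <- if (config@nAffectedTFs > 0L)
      sample(tfs, config@nAffectedTFs) else character()

    annotation <- GenomeAnnotation(operons = operons, tus = tus,
                                   tuOperon = tuOperon, interactions = net)
    truth <- list(chunks = chunks, chunkOf = chunkOf,
                  regulatorKeys = regulatorKeys(net, strict = FALSE),
                  affectedTFs = affected, tfs = tfs)
    list(annotation = annotation, truth = truth)
  })
}

#' Simulate a two-class expression series
#'
#' Per sample, each TF has a latent activity drawn from N(0, 1);
#' \code{classEffectSize} is added to the activities of the affected TFs in
#' the second class. A gene's expression is the sum of its regulators'
#' activities signed by role (+1 activation, -1 repression, 0 unknown, dual
#' drawn once per (TF, gene) as +-1), plus a noise term shared by all genes
#' of its chunk (sd \code{sigmaChunk}) and an independent per-gene term
#' (sd \code{sigmaGene}). Within-chunk correlation therefore rises with the
#' shared signal and chunk noise and falls with \code{sigmaGene}.
#'
#' @param annotation the simulated \linkS4class{GenomeAnnotation}.
#' @param truth the ground-truth list from \code{\link{simulateAnnotation}}.
#' @param config the \linkS4class{SimulationConfig}.
#' @param seed integer seed.
#' @return An \linkS4class{ExpressionSeries} with classes \code{"classA"}
#'   and \code{"classB"}; the latent TF activity matrix and the affected-TF
#'   list travel in \code{metadata}.
#' @export
simulateExpression <- function(annotation, truth, config,
                               seed = config@seed + 1L) {
  withSeed(seed, {
    genes <- unlist(annotation@operons, use.names = FALSE)
    nGenes <- length(genes)
    tfs <- truth$tfs
    nS <- 2L * config@nSamplesPerClass
    sampleIds <- sprintf("s%02d", seq_len(nS))
    classes <- rep(c("classA", "classB"), each = config@nSamplesPerClass)

    A <- matrix(rnorm(length(tfs) * nS), nrow = length(tfs),
                dimnames = list(tfs, sampleIds))
    if (length(truth$affectedTFs))
      A[truth$affectedTFs, classes == "classB"] <-
        A[truth$affectedTFs, classes == "classB"] + config@classEffectSize

    net <- annotation@interactions
    W <- matrix(0, nrow = nGenes, ncol = length(tfs),
                dimnames = list(genes, tfs))
    sgn <- c(activation = 1, repression = -1, unknown = 0)[net$role]
    isDual <- net$role == "dual"
    sgn[isDual] <- sample(c(-1, 1), sum(isDual), replace = TRUE)
    W[cbind(match(net$target, genes), match(net$tf, tfs))] <- sgn

    chunkNames <- names(truth$chunks)
    CN <- matrix(rnorm(length(chunkNames) * nS, sd = config@sigmaChunk),
                 nrow = length(chunkNames),
                 dimnames = list(chunkNames, sampleIds))
    E <- W %*% A + CN[truth$chunkOf[genes], , drop = FALSE] +
      matrix(rnorm(nGenes * nS, sd = config@sigmaGene), nrow = nGenes)
    dimnames(E) <- list(genes, sampleIds)

    se <- ExpressionSeries(E, stats::setNames(classes, sampleIds),
                           seriesId = paste0("sim", seed))
    S4Vectors::metadata(se)$activities <- A
    S4Vectors::metadata(se)$affectedTFs <- truth$affectedTFs
    se
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper drawing an annotation and a matching expression
#' series from one seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer seed.
#' @return A list with \code{annotation}, \code{truth} and \code{expr}.
#' @examples
#' sim <- simulateStudy(simulationConfig(nOperons = 30, nTFs = 5,
#'                                       targetsPerTFRange = c(2, 6)),
#'                      seed = 7)
#' sim$expr
#' @export
simulateStudy <- function(config = simulationConfig(), seed = config@seed) {
  sim <- simulateAnnotation(config, seed = seed)
  expr <- simulateExpression(sim$annotation, sim$truth, config,
                             seed = seed + 1L)
  c(sim, list(expr = expr))
}

#' Write a simulated study to flat files
#'
#' Writes the operon/TU/network tables, the expression matrix, the sample
#' labels and a ground-truth chunk sidecar in the package's TSV dialects,
#' so a simulated study can be consumed by the file-based entry points.
#'
#' @param sim a list from \code{\link{simulateStudy}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
writeStudy <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, c("operons.tsv", "tus.tsv", "network.tsv",
                        "expression.tsv", "labels.tsv", "chunks.tsv"))
  writeAnnotation(sim$annotation, p[1], p[2], p[3])
  vals <- exprValues(sim$expr)
  writeLines(c(paste(c("gene", colnames(vals)), collapse = "\t"),
               paste(rownames(vals),
                     apply(vals, 1L, paste, collapse = "\t"), sep = "\t")),
             p[4])
  lab <- sampleLabels(sim$expr)
  writeLines(paste(names(lab), lab, sep = "\t"), p[5])
  writeLines(paste(sim$truth$chunkOf, names(sim$truth$chunkOf), sep = "\t"),
             p[6])
  invisible(p)
}

#' Read an expression TSV with labels
#'
#' Expression TSV: header row of sample ids (first column \code{gene}),
#' one row per gene. Labels TSV: \code{sample_id<TAB>class}.
#'
#' @param exprPath expression TSV path.
#' @param labelsPath labels TSV path.
#' @param seriesId series identifier.
#' @return An \linkS4class{ExpressionSeries}.
#' @export
readExpressionSeries <- function(exprPath, labelsPath, seriesId = "series") {
  tab <- utils::read.delim(exprPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  lab <- utils::read.delim(labelsPath, header = FALSE,
                           stringsAsFactors = FALSE)
  ExpressionSeries(vals, stats::setNames(lab[[2]], lab[[1]]),
                   seriesId = seriesId)
}
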