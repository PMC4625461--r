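## Central S4 classes. Validity here checks structural well-formedness only;
## the full annotation invariants (gene-partition, TU contiguity, ...) live in
## validateAnnotation() so that report-only auditing of broken annotations is
## possible (parsers and constructors enforce them by default).

#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor median prcomp rnorm runif sd pchisq pnorm
#'   hclust cutree as.dist setNames
#' @importFrom utils read.delim
NULL

ROLE_LEVELS <- c("activation", "repression", "dual", "unknown")
ROLE_CODES <- c(activation = "+", repression = "-", dual = "+-", unknown = "?")
SET_TYPES <- c("OPR", "TU", "COPR", "TF", "REG", "SREG", "EXTERNAL", "RANDOMIZED")

emptyInteractions <- function() {
  data.frame(tf = character(), target = character(), role = character(),
             stringsAsFactors = FALSE)
}

#' GenomeAnnotation: operons, transcription units and regulatory interactions
#'
#' Container for a prokaryotic regulatory annotation: operons (ordered gene
#' lists in transcription order), transcription units (contiguous slices of
#' their parent operon, one per promoter), and TF-target interactions with a
#' regulatory role (activation, repression, dual or unknown). This is the
#' substrate from which all gene-set families are built.
#'
#' Gene identifiers are opaque, case-sensitive strings; positions are list
#' indices, no genomic coordinates are stored. An operon with no listed
#' transcription unit is treated downstream as carrying one implicit
#' transcription unit spanning the whole operon.
#'
#' @slot operons named list; each element a character vector of gene ids in
#'   transcription order, names are operon ids.
#' @slot tus named list of character vectors (TU member genes), names are
#'   TU ids.
#' @slot tuOperon named character vector mapping TU id to parent operon id.
#' @slot interactions data.frame with columns \code{tf}, \code{target},
#'   \code{role}; at most one row per (tf, target) pair after merging.
#'
#' @aliases GenomeAnnotation-class
#' @export
setClass("GenomeAnnotation",
         representation(operons = "list", tus = "list",
                        tuOperon = "character", interactions = "data.frame"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  if (length(object@operons) && is.null(names(object@operons)))
    msg <- c(msg, "operons must be a named list")
  if (length(object@tus) && is.null(names(object@tus)))
    msg <- c(msg, "tus must be a named list")
  if (!identical(sort(names(object@tus)), sort(names(object@tuOperon))))
    msg <- c(msg, "tuOperon must be named by the TU ids")
  if (!all(c("tf", "target", "role") %in% colnames(object@interactions)))
    msg <- c(msg, "interactions needs columns tf, target, role")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param operons named list of character vectors (genes in transcription
#'   order), names are operon ids.
#' @param tus named list of character vectors (TU member genes).
#' @param tuOperon named character vector, TU id -> operon id.
#' @param interactions data.frame with columns tf, target, role (roles are
#'   "activation", "repression", "dual", "unknown"); duplicate (tf, target)
#'   rows must already be merged (see \code{\link{readNetwork}}).
#' @param check if TRUE (default), run \code{\link{validateAnnotation}} and
#'   stop on any violation.
#' @return A \code{GenomeAnnotation} object.
#' @examples
#' ann <- GenomeAnnotation(
#'   operons = list(bcsABZC = c("bcsA", "bcsB", "bcsZ", "bcsC")),
#'   tus = list(bcsABZC = c("bcsA", "bcsB", "bcsZ", "bcsC"),
#'              bcsBZ = c("bcsB", "bcsZ")),
#'   tuOperon = c(bcsABZC = "bcsABZC", bcsBZ = "bcsABZC"))
#' ann
#' @export
GenomeAnnotation <- function(operons = list(), tus = list(),
                             tuOperon = character(),
                             interactions = emptyInteractions(),
                             check = TRUE) {
  interactions$tf <- as.character(interactions$tf)
  interactions$target <- as.character(interactions$target)
  interactions$role <- as.character(interactions$role)
  rownames(interactions) <- NULL
  obj <- new("GenomeAnnotation", operons = operons, tus = tus,
             tuOperon = tuOperon, interactions = interactions)
  if (check) {
    rep <- validateAnnotation(obj)
    if (length(rep$violations))
      stop("invalid annotation:\n  ",
           paste(rep$violations, collapse = "\n  "))
  }
  obj
}

#' GeneSetFamily: a typed, named collection of gene sets
#'
#' The central object of the package: a family of maximal gene sets of one
#' defining type. Operon-based families (OPR, COPR) and the regulon families
#' (REG, SREG) are partitions; TU and TF families may contain overlapping
#' sets. Set membership is unordered; singleton sets are retained (they are
#' excluded only where an analysis says so, e.g. correlation sampling).
#'
#' @slot setType one of OPR, TU, COPR, TF, REG, SREG, EXTERNAL, RANDOMIZED.
#' @slot sets named list of character vectors (member gene ids).
#' @slot descriptions character vector parallel to \code{sets}.
#' @slot provenance free-text origin (source annotation, seed if randomized).
#'
#' @aliases GeneSetFamily-class
#' @export
setClass("GeneSetFamily",
         representation(setType = "character", sets = "list",
                        descriptions = "character", provenance = "character"))

setValidity("GeneSetFamily", function(object) {
  msg <- character()
  if (length(object@setType) != 1L || !object@setType %in% SET_TYPES)
    msg <- c(msg, paste("setType must be one of:",
                        paste(SET_TYPES, collapse = ", ")))
  nm <- names(object@sets)
  if (length(object@sets)) {
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "sets must have unique non-empty names")
    sizes <- lengths(object@sets)
    if (any(sizes == 0L))
      msg <- c(msg, "gene sets must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "gene sets must not contain duplicate members")
  }
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must parallel sets")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetFamily
#'
#' @param setType family type, one of \code{"OPR"}, \code{"TU"},
#'   \code{"COPR"}, \code{"TF"}, \code{"REG"}, \code{"SREG"},
#'   \code{"EXTERNAL"}, \code{"RANDOMIZED"}.
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector parallel to \code{sets}.
#' @param provenance free-text origin string.
#' @return A \code{GeneSetFamily}.
#' @export
GeneSetFamily <- function(setType, sets = list(), descriptions = NULL,
                          provenance = "") {
  sets <- lapply(sets, as.character)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("GeneSetFamily", setType = setType, sets = sets,
      descriptions = as.character(descriptions), provenance = provenance)
}

#' ExpressionSeries: a labelled genes-by-samples expression matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' \code{"exprs"} (genes in rows, samples in columns) and a mandatory
#' \code{label} column in \code{colData} assigning each sample a phenotype
#' class. A series id travels in \code{metadata}; binary datasets produced by
#' \code{\link{buildPool}} additionally carry their class pair there.
#'
#' @aliases ExpressionSeries-class
#' @export
setClass("ExpressionSeries", contains = "SummarizedExperiment")

setValidity("ExpressionSeries", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd))
    msg <- c(msg, "colData column 'label' is required")
  else if (anyNA(cd$label) || any(!nzchar(as.character(cd$label))))
    msg <- c(msg, "every sample needs a non-empty phenotype label")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionSeries
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param labels phenotype class per sample: either named by sample id or
#'   positionally aligned with \code{colnames(values)}.
#' @param seriesId identifier of the series (used to qualify phenotype
#'   classes when pooling several series).
#' @return An \code{ExpressionSeries}.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' es <- ExpressionSeries(m, c(s1 = "wt", s2 = "wt", s3 = "mut", s4 = "mut"))
#' sampleLabels(es)
#' @export
ExpressionSeries <- function(values, labels, seriesId = "series") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("no label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("labels must be named or match the number of samples")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   row.names = colnames(values)))
  S4Vectors::metadata(se)$seriesId <- seriesId
  new("ExpressionSeries", se)
}

#' FeatureMatrix: features-by-samples input to a classifier
#'
#' The result of a representation step: set-level aggregated features,
#' gene-level union features, or TF-as-single-gene features. Rows are
#' features (set names or gene ids), columns are samples.
#'
#' @slot values numeric matrix with feature rownames and sample colnames.
#' @slot kind one of \code{"set_level"}, \code{"gene_level_union"},
#'   \code{"tf_genes"}.
#'
#' @aliases FeatureMatrix-class
#' @export
setClass("FeatureMatrix",
         representation(values = "matrix", kind = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (is.null(rownames(object@values)) || anyDuplicated(rownames(object@values)))
    msg <- c(msg, "feature ids must be unique rownames")
  if (!object@kind %in% c("set_level", "gene_level_union", "tf_genes"))
    msg <- c(msg, "unknown representation kind")
  if (length(msg)) msg else TRUE
})

FeatureMatrix <- function(values, kind) {
  new("FeatureMatrix", values = as.matrix(values), kind = kind)
}

#' SimulationConfig: parameters of the synthetic genome and expression model
#'
#' Describes a synthetic prokaryotic study: a genome of operons with internal
#' promoters (spawning suffix transcription units), a TF network with roles,
#' and a two-class expression series in which phenotype classes differ by a
#' shift in the latent activity of a few affected TFs. Genes belonging to the
#' same always-co-transcribed chunk share a chunk-level noise term, which is
#' what makes within-chunk expression highly correlated.
#'
#' Defaults emulate the regime of small bacterial microarray studies and the
#' size structure of the E. coli operon map: ~2000 genes in 1200 operons
#' whose sizes follow a truncated geometric law with mean 1.7 (about 60%
#' single-gene operons, maximum 16), an internal promoter at a quarter of
#' the inter-gene boundaries, 40 TFs each targeting 3-26 transcription
#' units (roughly 25 genes), and 4+4 samples per binary dataset.
#'
#' @slot nOperons number of operons.
#' @slot operonSizeRange integer min/max genes per operon (truncation
#'   bounds of the size law).
#' @slot operonSizeMean target mean operon size of the truncated geometric
#'   size law (set equal to the midpoint range for a degenerate law).
#' @slot pInternalPromoter probability of a promoter at each internal
#'   inter-gene boundary (each spawns a suffix TU).
#' @slot nTFs number of transcription factors (drawn from the gene universe).
#' @slot targetsPerTFRange integer min/max targets per TF.
#' @slot targetUnits \code{"tu"} (default; a TF targets whole transcription
#'   units, all member genes inherit the interaction) or \code{"gene"}
#'   (independent per-gene draws).
#' @slot roleProbs named probabilities over activation/repression/dual/unknown
#'   for a TF's characteristic role.
#' @slot pRoleDeviation probability that an individual target deviates from
#'   its TF's characteristic role (redrawn from \code{roleProbs}); TFs act
#'   predominantly as activators or repressors, so this is small.
#' @slot nSamplesPerClass samples per phenotype class.
#' @slot classEffectSize shift (in sd units) added to the latent activity of
#'   affected TFs in the second class.
#' @slot nAffectedTFs number of TFs whose activity differs between classes.
#' @slot sigmaChunk sd of the noise term shared by all genes of a chunk.
#' @slot sigmaGene sd of the per-gene noise term.
#' @slot seed default seed used when none is passed to the generator.
#'
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
         representation(nOperons = "integer", operonSizeRange = "integer",
                        operonSizeMean = "numeric",
                        pInternalPromoter = "numeric", nTFs = "integer",
                        targetsPerTFRange = "integer", targetUnits = "character",
                        roleProbs = "numeric", pRoleDeviation = "numeric",
                        nSamplesPerClass = "integer",
                        classEffectSize = "numeric", nAffectedTFs = "integer",
                        sigmaChunk = "numeric", sigmaGene = "numeric",
                        seed = "integer"),
         prototype(nOperons = 1200L, operonSizeRange = c(1L, 16L),
                   operonSizeMean = 1.7,
                   pInternalPromoter = 0.25, nTFs = 40L,
                   targetsPerTFRange = c(3L, 26L), targetUnits = "tu",
                   roleProbs = c(activation = 0.45, repression = 0.40,
                                 dual = 0.05, unknown = 0.10),
                   pRoleDeviation = 0.13,
                   nSamplesPerClass = 4L, classEffectSize = 4,
                   nAffectedTFs = 5L, sigmaChunk = 1.0, sigmaGene = 0.7,
                   seed = 1L))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nOperons < 1L) msg <- c(msg, "nOperons must be positive")
  if (length(object@operonSizeRange) != 2L ||
      object@operonSizeRange[1] < 1L ||
      object@operonSizeRange[1] > object@operonSizeRange[2])
    msg <- c(msg, "operonSizeRange must be an increasing positive pair")
  if (object@operonSizeMean < object@operonSizeRange[1] ||
      object@operonSizeMean > object@operonSizeRange[2])
    msg <- c(msg, "operonSizeMean must lie within operonSizeRange")
  if (object@pInternalPromoter < 0 || object@pInternalPromoter > 1)
    msg <- c(msg, "pInternalPromoter must be in [0, 1]")
  if (length(object@targetsPerTFRange) != 2L ||
      object@targetsPerTFRange[1] < 1L ||
      object@targetsPerTFRange[1] > object@targetsPerTFRange[2])
    msg <- c(msg, "targetsPerTFRange must be an increasing positive pair")
  if (!object@targetUnits %in% c("tu", "gene"))
    msg <- c(msg, "targetUnits must be 'tu' or 'gene'")
  if (!identical(sort(names(object@roleProbs)), sort(ROLE_LEVELS)) ||
      any(object@roleProbs < 0) || abs(sum(object@roleProbs) - 1) > 1e-8)
    msg <- c(msg, "roleProbs must be a probability vector over the four roles")
  if (object@pRoleDeviation < 0 || object@pRoleDeviation > 1)
    msg <- c(msg, "pRoleDeviation must be in [0, 1]")
  if (object@nSamplesPerClass < 2L)
    msg <- c(msg, "need at least 2 samples per class")
  if (object@nAffectedTFs < 0L || object@nAffectedTFs > object@nTFs)
    msg <- c(msg, "nAffectedTFs must be between 0 and nTFs")
  if (object@sigmaChunk < 0 || object@sigmaGene < 0)
    msg <- c(msg, "noise sds must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' All arguments default to the values documented in
#' \linkS4class{SimulationConfig}.
#'
#' @param nOperons,operonSizeRange,operonSizeMean,pInternalPromoter,nTFs,targetsPerTFRange
#'   genome parameters (see class documentation).
#' @param targetUnits "tu" or "gene" targeting mode.
#' @param roleProbs named probability vector over the four roles.
#' @param pRoleDeviation per-target probability of deviating from the TF's
#'   characteristic role.
#' @param nSamplesPerClass,classEffectSize,nAffectedTFs,sigmaChunk,sigmaGene
#'   expression-model parameters.
#' @param seed default generator seed.
#' @return A \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nOperons = 20, nTFs = 4, nAffectedTFs = 2,
#'                         targetsPerTFRange = c(2, 5))
#' cfg
#' @export
simulationConfig <- function(nOperons = 1200, operonSizeRange = c(1, 16),
                             operonSizeMean = NULL,
                             pInternalPromoter = 0.25, nTFs = 40,
                             targetsPerTFRange = c(3, 26),
                             targetUnits = "tu",
                             roleProbs = c(activation = 0.45,
                                           repression = 0.40,
                                           dual = 0.05, unknown = 0.10),
                             pRoleDeviation = 0.13,
                             nSamplesPerClass = 4, classEffectSize = 4,
                             nAffectedTFs = 5, sigmaChunk = 1.0,
                             sigmaGene = 0.7, seed = 1) {
  if (is.null(operonSizeMean))    # E. coli-like skew, clamped to the range
    operonSizeMean <- min(max(1.7, operonSizeRange[1]), operonSizeRange[2])
  new("SimulationConfig",
      nOperons = as.integer(nOperons),
      operonSizeRange = as.integer(operonSizeRange),
      operonSizeMean = operonSizeMean,
      pInternalPromoter = pInternalPromoter,
      nTFs = as.integer(nTFs),
      targetsPerTFRange = as.integer(targetsPerTFRange),
      targetUnits = targetUnits,
      roleProbs = roleProbs[ROLE_LEVELS],
      pRoleDeviation = pRoleDeviation,
      nSamplesPerClass = as.integer(nSamplesPerClass),
      classEffectSize = classEffectSize,
      nAffectedTFs = as.integer(nAffectedTFs),
      sigmaChunk = sigmaChunk, sigmaGene = sigmaGene,
      seed = as.integer(seed))
}
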