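## Accessors and show methods for the core classes.

#' @rdname GenomeAnnotation
#' @export
setMethod("operons", "GenomeAnnotation", function(x) x@operons)

#' @rdname GenomeAnnotation
#' @export
setMethod("transcriptionUnits", "GenomeAnnotation", function(x) {
  lst <- x@tus
  attr(lst, "operon") <- x@tuOperon
  lst
})

#' @rdname GenomeAnnotation
#' @export
setMethod("interactions", "GenomeAnnotation", function(x) x@interactions)

#' @rdname GenomeAnnotation
#' @export
setMethod("geneUniverse", "GenomeAnnotation", function(x) {
  sort(unique(c(unlist(x@operons, use.names = FALSE),
                unlist(x@tus, use.names = FALSE),
                x@interactions$tf, x@interactions$target)))
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation\n",
      "  operons:      ", length(object@operons), "\n",
      "  TUs:          ", length(object@tus), "\n",
      "  interactions: ", nrow(object@interactions),
      " (", length(unique(object@interactions$tf)), " TFs)\n",
      "  genes:        ", length(geneUniverse(object)), "\n", sep = "")
})

#' @rdname GeneSetFamily
#' @export
setMethod("setType", "GeneSetFamily", function(x) x@setType)

#' @rdname GeneSetFamily
#' @export
setMethod("geneSets", "GeneSetFamily", function(x) x@sets)

#' @rdname GeneSetFamily
#' @export
setMethod("setSizes", "GeneSetFamily", function(x) lengths(x@sets))

#' @rdname GeneSetFamily
#' @export
setMethod("provenance", "GeneSetFamily", function(x) x@provenance)

#' @rdname GeneSetFamily
#' @export
setMethod("geneUniverse", "GeneSetFamily", function(x) {
  sort(unique(unlist(x@sets, use.names = FALSE)))
})

#' @rdname GeneSetFamily
#' @export
setMethod("length", "GeneSetFamily", function(x) length(x@sets))

#' @rdname GeneSetFamily
#' @export
setMethod("names", "GeneSetFamily", function(x) names(x@sets))

#' @rdname GeneSetFamily
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetFamily", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetFamily", function(object) {
  sz <- setSizes(object)
  cat("GeneSetFamily of type ", object@setType, "\n",
      "  sets:  ", length(object@sets), "\n",
      "  genes: ", length(geneUniverse(object)), "\n", sep = "")
  if (length(sz))
    cat("  sizes: median ", median(sz), ", mean ", round(mean(sz), 3),
        ", max ", max(sz), "\n", sep = "")
  if (nzchar(object@provenance))
    cat("  provenance: ", object@provenance, "\n", sep = "")
})

#' @rdname ExpressionSeries
#' @export
setMethod("exprValues", "ExpressionSeries", function(x) {
  SummarizedExperiment::assay(x, "exprs")
})

#' @rdname ExpressionSeries
#' @export
setMethod("sampleLabels", "ExpressionSeries", function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$label),
                  colnames(x))
})

#' @rdname ExpressionSeries
#' @export
setMethod("seriesId", "ExpressionSeries", function(x) {
  id <- S4Vectors::metadata(x)$seriesId
  if (is.null(id)) NA_character_ else id
})

#' @rdname ExpressionSeries
#' @export
setMethod("classPair", "ExpressionSeries", function(x) {
  S4Vectors::metadata(x)$classPair
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureKind", "FeatureMatrix", function(x) x@kind)

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix (", object@kind, ")\n",
      "  features: ", nrow(object@values), "\n",
      "  samples:  ", ncol(object@values), "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n",
      "  genome:     ", object@nOperons, " operons of ",
      object@operonSizeRange[1], "-", object@operonSizeRange[2],
      " genes, P(internal promoter) = ", object@pInternalPromoter, "\n",
      "  network:    ", object@nTFs, " TFs x ",
      object@targetsPerTFRange[1], "-", object@targetsPerTFRange[2],
      " targets (", object@targetUnits, "-level)\n",
      "  expression: ", 2L * object@nSamplesPerClass, " samples (",
      object@nSamplesPerClass, "+", object@nSamplesPerClass,
      "), effect ", object@classEffectSize, " sd on ",
      object@nAffectedTFs, " TFs\n",
      "  noise:      sigmaChunk = ", object@sigmaChunk,
      ", sigmaGene = ", object@sigmaGene, "\n", sep = "")
})
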