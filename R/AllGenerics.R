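#' @rdname GenomeAnnotation
#' @param x object to access.
#' @export
setGeneric("operons", function(x) standardGeneric("operons"))

#' @rdname GenomeAnnotation
#' @export
setGeneric("transcriptionUnits",
           function(x) standardGeneric("transcriptionUnits"))

#' @rdname GenomeAnnotation
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname GenomeAnnotation
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname GeneSetFamily
#' @param x object to access.
#' @export
setGeneric("setType", function(x) standardGeneric("setType"))

#' @rdname GeneSetFamily
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetFamily
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' @rdname GeneSetFamily
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ExpressionSeries
#' @param x object to access.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionSeries
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname ExpressionSeries
#' @export
setGeneric("seriesId", function(x) standardGeneric("seriesId"))

#' @rdname ExpressionSeries
#' @export
setGeneric("classPair", function(x) standardGeneric("classPair"))

#' @rdname FeatureMatrix-class
#' @param x object to access.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
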