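## Gene-level -> set-level feature transformation and the baseline
## representations used in comparisons.

#' Aggregate expression over gene sets
#'
#' Converts a genes-by-samples expression matrix into a sets-by-samples
#' feature matrix: one feature per set with at least one measured member,
#' its value per sample aggregating the member-gene expressions. Sets are
#' aggregated over their intersection with the measured genes; sets with no
#' measured member are dropped with a warning.
#'
#' Aggregation methods:
#' \describe{
#'   \item{mean}{arithmetic average of member expressions (the default used
#'     throughout the classification protocol).}
#'   \item{median}{member-wise median.}
#'   \item{pc1}{projection of the samples onto the first principal component
#'     of the gene-centered within-set submatrix, with the sign fixed so the
#'     loading sum is non-negative, plus the set's grand mean (so a
#'     singleton set reproduces its gene's expression row exactly).}
#' }
#'
#' @param expr an \linkS4class{ExpressionSeries}.
#' @param family a \linkS4class{GeneSetFamily}.
#' @param method \code{"mean"}, \code{"median"} or \code{"pc1"}.
#' @return A \linkS4class{FeatureMatrix} of kind \code{"set_level"}.
#' @examples
#' m <- matrix(c(1, 3, 2, 4), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' es <- ExpressionSeries(m, c(s1 = "a", s2 = "b"))
#' fam <- GeneSetFamily("EXTERNAL", list(s = c("g1", "g2")))
#' featureValues(aggregateSets(es, fam))   # 2 and 3
#' @export
aggregateSets <- function(expr, family, method = c("mean", "median", "pc1")) {
  method <- match.arg(method)
  if (!length(family@sets)) stop("family has no sets")
  vals <- exprValues(expr)
  measured <- lapply(family@sets, intersect, rownames(vals))
  empty <- lengths(measured) == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) with no measured member dropped")
    measured <- measured[!empty]
  }
  if (!length(measured)) stop("no set has a measured member")
  rows <- vapply(measured, function(g) {
    sub <- vals[g, , drop = FALSE]
    switch(method,
           mean = colMeans(sub),
           median = apply(sub, 2L, median),
           pc1 = pc1Row(sub))
  }, numeric(ncol(vals)))
  rows <- t(rows)
  dimnames(rows) <- list(names(measured), colnames(vals))
  FeatureMatrix(rows, "set_level")
}

## First-PC aggregation of one genes-by-samples submatrix. Samples are the
## observations, genes the variables; the gene-centered scores are shifted
## by the grand mean to keep the feature on the expression scale.
pc1Row <- function(sub) {
  if (nrow(sub) == 1L) return(sub[1L, ])
  x <- t(sub)                               # samples x genes
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  v <- sv$v[, 1L]
  if (sum(v) < 0) v <- -v
  as.numeric(xc %*% v) + mean(sub)
}

#' Gene-level union baseline
#'
#' The gene-level counterpart of a set-level representation: features are
#' the individual genes in the union of the family's sets (intersected with
#' the measured genes), values copied unchanged. This gives the gene-level
#' classifier exactly the same input information as the set-level one. For
#' a COPR family over its source annotation the union is all operon genes.
#'
#' @inheritParams aggregateSets
#' @return A \linkS4class{FeatureMatrix} of kind \code{"gene_level_union"}.
#' @export
geneLevelUnion <- function(expr, family) {
  vals <- exprValues(expr)
  genes <- intersect(rownames(vals),
                     unique(unlist(family@sets, use.names = FALSE)))
  if (!length(genes))
    stop("no gene of the family is present in the expression matrix")
  FeatureMatrix(vals[genes, , drop = FALSE], "gene_level_union")
}

#' TF-as-single-genes baseline
#'
#' Represents each sample by the measured expression of the transcription
#' factors themselves (the genes acting as regulators in the network),
#' rather than by aggregates over their targets. TFs absent from the
#' expression matrix are excluded with a warning.
#'
#' @param expr an \linkS4class{ExpressionSeries}.
#' @param annotation a \linkS4class{GenomeAnnotation} providing the network.
#' @return A \linkS4class{FeatureMatrix} of kind \code{"tf_genes"}.
#' @export
tfGeneFeatures <- function(expr, annotation) {
  tfs <- sort(unique(annotation@interactions$tf))
  if (!length(tfs)) stop("annotation has no regulatory interactions")
  vals <- exprValues(expr)
  present <- intersect(tfs, rownames(vals))
  if (!length(present)) stop("no TF is present in the expression matrix")
  if (length(present) < length(tfs))
    warning(length(tfs) - length(present), " TF(s) not measured, excluded")
  FeatureMatrix(vals[present, , drop = FALSE], "tf_genes")
}

#' Ad-hoc gene sets by hierarchical clustering (CLUST baseline)
#'
#' Builds k data-driven gene sets by average-linkage agglomerative
#' clustering of the genes with distance 1 - Pearson correlation across the
#' supplied samples, cutting the dendrogram at exactly k clusters. By the
#' protocol's contract this must be called on training samples only, with k
#' matched to the size of the gene-set family it is compared against.
#'
#' @param exprTraining an \linkS4class{ExpressionSeries} restricted to the
#'   training samples.
#' @param k number of clusters, between 1 and the number of genes.
#' @return A \linkS4class{GeneSetFamily} of type \code{"EXTERNAL"} with k
#'   sets named \code{clust1..clustk}.
#' @export
clustFamily <- function(exprTraining, k) {
  vals <- exprValues(exprTraining)
  if (k < 1L || k > nrow(vals))
    stop("k must be between 1 and the number of genes")
  cc <- suppressWarnings(cor(t(vals)))
  cc[!is.finite(cc)] <- 0          # zero-variance genes: treat as uncorrelated
  hc <- hclust(as.dist(1 - cc), method = "average")
  cl <- cutree(hc, k = k)
  sets <- split(rownames(vals), cl)
  names(sets) <- paste0("clust", names(sets))
  GeneSetFamily("EXTERNAL", sets,
                descriptions = paste0("hierarchical cluster ",
                                      seq_along(sets)),
                provenance = paste0("average-linkage clustering, k = ", k))
}
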