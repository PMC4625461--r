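## Builders for the six gene-set families derived from operon/TU structure
## and the TF network, plus randomized controls, family statistics and GMT
## I/O. All families are maximal by construction: every gene satisfying a
## set's defining condition is a member.

#' Operon gene sets (OPR)
#'
#' One set per operon, containing the genes located in that operon. Operons
#' partition the annotated genes, so the family is disjoint.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return A \linkS4class{GeneSetFamily} of type \code{"OPR"}.
#' @family gene-set builders
#' @export
buildOPR <- function(annotation) {
  GeneSetFamily("OPR", annotation@operons,
                descriptions = paste0("operon ", names(annotation@operons)),
                provenance = "operon annotation")
}

#' Transcription-unit gene sets (TU)
#'
#' One set per distinct transcription-unit member set: the genes transcribed
#' from a single promoter. TUs may overlap and nest, so the family is not
#' disjoint. Two promoters yielding identical member lists collapse to one
#' set (the set, not the promoter, is the feature unit); the surviving name
#' is the lexicographically smallest TU id. Operons without a listed TU
#' contribute their implicit whole-operon TU.
#'
#' @inheritParams buildOPR
#' @return A \linkS4class{GeneSetFamily} of type \code{"TU"}.
#' @family gene-set builders
#' @export
buildTU <- function(annotation) {
  ids <- character(); ops <- character(); keys <- character()
  members <- list()
  for (op in names(annotation@operons)) {
    tus <- effectiveTUs(annotation, op)
    for (id in names(tus)) {
      ids <- c(ids, id); ops <- c(ops, op)
      keys <- c(keys, paste(sort(tus[[id]]), collapse = "\r"))
      members[[length(members) + 1L]] <- tus[[id]]
    }
  }
  if (!length(ids))
    return(GeneSetFamily("TU", provenance = "TU annotation"))
  sets <- list(); desc <- character()
  for (key in unique(keys)) {
    sel <- which(keys == key)
    pick <- sel[order(ids[sel])][1L]   # smallest TU id survives a dedup
    sets[[ids[pick]]] <- members[[pick]]
    desc <- c(desc, paste0("transcription unit ", ids[pick],
                           " of operon ", ops[pick]))
  }
  GeneSetFamily("TU", sets, descriptions = desc,
                provenance = "TU annotation")
}

#' Continuous operon subsequence gene sets (COPR)
#'
#' Splits each operon into its maximal always-co-transcribed chunks: a cut
#' is placed at every inter-gene boundary where some TU of the operon starts
#' or ends (a TU over positions i..j cuts before i and after j), and chunks
#' are the maximal runs between consecutive cuts. Equivalently, no promoter
#' lies between two genes of a chunk. The chunks partition each operon, and
#' therefore all operon genes; merging two adjacent chunks would always
#' place a TU start or end strictly inside.
#'
#' @inheritParams buildOPR
#' @return A \linkS4class{GeneSetFamily} of type \code{"COPR"}; set names
#'   are \code{<operon>.<chunk index>}.
#' @family gene-set builders
#' @export
buildCOPR <- function(annotation) {
  sets <- list(); desc <- character()
  for (op in names(annotation@operons)) {
    genes <- annotation@operons[[op]]
    n <- length(genes)
    cut <- logical(max(n - 1L, 0L))    # cut[b]: boundary between b and b+1
    for (tu in effectiveTUs(annotation, op)) {
      i <- match(tu[1], genes)
      j <- i + length(tu) - 1L
      if (i > 1L) cut[i - 1L] <- TRUE
      if (j < n) cut[j] <- TRUE
    }
    chunkId <- cumsum(c(1L, as.integer(cut)))
    for (k in unique(chunkId)) {
      nm <- paste0(op, ".", k)
      sets[[nm]] <- genes[chunkId == k]
      desc[nm] <- paste0("chunk ", k, " of operon ", op)
    }
  }
  GeneSetFamily("COPR", sets, descriptions = unname(desc),
                provenance = "operon + TU annotation")
}

roleSuffix <- c(activation = "act", repression = "rep",
                dual = "dual", unknown = "unk")

#' Transcription-factor gene sets (TF)
#'
#' One set per (TF, role) pair with at least one target: the genes sharing a
#' regulating TF whose influence (activation, repression, dual, unknown) is
#' the same for all members. A single TF therefore yields at most four sets.
#' Sets of different TFs may overlap.
#'
#' @inheritParams buildOPR
#' @return A \linkS4class{GeneSetFamily} of type \code{"TF"}; set names are
#'   \code{<tf>.<act|rep|dual|unk>}.
#' @family gene-set builders
#' @export
buildTF <- function(annotation) {
  net <- annotation@interactions
  sets <- list(); desc <- character()
  if (nrow(net)) {
    for (tf in sort(unique(net$tf))) {
      sub <- net[net$tf == tf, , drop = FALSE]
      for (role in ROLE_LEVELS) {
        tg <- sub$target[sub$role == role]
        if (!length(tg)) next
        nm <- paste0(tf, ".", roleSuffix[[role]])
        sets[[nm]] <- tg
        desc[nm] <- paste0("targets of ", tf, " with role ", role)
      }
    }
  }
  GeneSetFamily("TF", sets, descriptions = unname(desc),
                provenance = "regulatory network")
}

## Regulator keys per regulated gene. strict=FALSE keys by TF set only,
## strict=TRUE by the set of (tf, role) pairs.
regulatorKeys <- function(net, strict = FALSE) {
  tok <- if (strict) paste0(net$tf, "(", ROLE_CODES[net$role], ")") else net$tf
  keys <- vapply(split(tok, net$target),
                 function(x) paste(sort(unique(x)), collapse = "+"), "")
  keys
}

buildRegulonFamily <- function(annotation, strict) {
  net <- annotation@interactions
  type <- if (strict) "SREG" else "REG"
  if (!nrow(net))
    return(GeneSetFamily(type, provenance = "regulatory network"))
  keys <- regulatorKeys(net, strict = strict)
  grp <- split(names(keys), keys)
  grp <- grp[sort(names(grp))]
  nms <- paste0(type, "|", names(grp))
  sets <- lapply(grp, identity)
  names(sets) <- nms
  GeneSetFamily(type, sets,
                descriptions = paste0("regulated by ", names(grp)),
                provenance = "regulatory network")
}

#' Regulon gene sets (REG)
#'
#' Partitions the regulated genes (those with at least one interaction) into
#' equivalence classes of genes regulated by exactly the same set of TFs,
#' regulatory roles ignored. Unregulated genes are excluded.
#'
#' @inheritParams buildOPR
#' @return A \linkS4class{GeneSetFamily} of type \code{"REG"}.
#' @family gene-set builders
#' @export
buildREG <- function(annotation) buildRegulonFamily(annotation, strict = FALSE)

#' Strict-regulon gene sets (SREG)
#'
#' Like \code{\link{buildREG}}, but the equivalence key is the set of
#' (TF, role) pairs: members must share the same regulators, each with the
#' same role for all of them. Every strict regulon is contained in exactly
#' one regulon, i.e. SREG refines the REG partition.
#'
#' @inheritParams buildOPR
#' @return A \linkS4class{GeneSetFamily} of type \code{"SREG"}.
#' @family gene-set builders
#' @export
buildSREG <- function(annotation) buildRegulonFamily(annotation, strict = TRUE)

#' Randomized control family
#'
#' Shuffles genes among the sets of a family while keeping the size
#' proportions (and the entire overlap structure) unchanged: a uniformly
#' random bijection on the union of member genes is drawn under the seed and
#' every membership is relabelled through it. Set count, the size multiset,
#' and all pairwise intersection cardinalities are invariant. These controls
#' isolate plain dimensionality reduction from biologically coherent
#' grouping.
#'
#' @param family a \linkS4class{GeneSetFamily}.
#' @param seed integer seed for the permutation draw.
#' @param permutation optional explicit bijection (character vector of new
#'   ids named by old ids) overriding the seeded draw; useful for tests.
#' @return A \linkS4class{GeneSetFamily} of type \code{"RANDOMIZED"} whose
#'   set names match the input.
#' @export
randomizeFamily <- function(family, seed = 1L, permutation = NULL) {
  if (!length(family@sets)) stop("cannot randomize an empty family")
  universe <- sort(unique(unlist(family@sets, use.names = FALSE)))
  if (is.null(permutation)) {
    permutation <- withSeed(seed, sample(universe))
    names(permutation) <- universe
  } else {
    if (!setequal(names(permutation), universe) ||
        !setequal(permutation, universe))
      stop("permutation must be a bijection on the family's gene universe")
  }
  sets <- lapply(family@sets, function(s) unname(permutation[s]))
  GeneSetFamily("RANDOMIZED", sets, descriptions = family@descriptions,
                provenance = paste0("randomized from ", family@setType,
                                    ", seed ", seed))
}

#' Family summary statistics
#'
#' Counts and size statistics of a family: number of sets, number of genes
#' contained in at least one set, and median/mean/max set size. Because sets
#' of overlapping families share genes, \code{nGenes / nSets} need not equal
#' the mean size.
#'
#' @param family a \linkS4class{GeneSetFamily}.
#' @return A one-row data.frame with columns \code{setType}, \code{nSets},
#'   \code{nGenes}, \code{medianSize}, \code{meanSize}, \code{maxSize}
#'   (size statistics are \code{NA} for an empty family).
#' @export
familyStats <- function(family) {
  sz <- setSizes(family)
  data.frame(setType = family@setType,
             nSets = length(sz),
             nGenes = length(unique(unlist(family@sets, use.names = FALSE))),
             medianSize = if (length(sz)) median(sz) else NA_real_,
             meanSize = if (length(sz)) mean(sz) else NA_real_,
             maxSize = if (length(sz)) max(sz) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line,
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes
#' within a row are deduplicated with a warning; rows with fewer than three
#' fields are an error.
#'
#' @param path GMT file path.
#' @param setType family type to stamp on the result (default
#'   \code{"EXTERNAL"}, e.g. for GO/KEGG baselines supplied as GMT).
#' @return A \linkS4class{GeneSetFamily}.
#' @export
readGMT <- function(path, setType = "EXTERNAL") {
  d <- readDataLines(path)
  sets <- list(); desc <- character()
  for (k in seq_along(d$lines)) {
    f <- strsplit(d$lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", d$lineno[k], ": expected at least 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", f[1], "': duplicate genes deduplicated")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  GeneSetFamily(setType, sets, descriptions = unname(desc),
                provenance = path)
}

#' Write a family as GMT
#'
#' @param family a \linkS4class{GeneSetFamily}.
#' @param path output path.
#' @return Invisibly, the family. Writing then reading yields an equal
#'   family (up to the stamped type/provenance).
#' @export
writeGMT <- function(family, path) {
  desc <- family@descriptions
  desc[!nzchar(desc)] <- "na"
  writeLines(paste0(names(family@sets), "\t", desc, "\t",
                    vapply(family@sets, paste, "", collapse = "\t")),
             path)
  invisible(family)
}
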