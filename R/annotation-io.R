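## Parsers, validators and writers for RegulonDB-style flat annotation files.
##
## File dialects ('#' comments, UTF-8, tab-separated):
##   operons: operon_id <TAB> gene1,gene2,...        (transcription order)
##   TUs:     tu_id <TAB> operon_id <TAB> gene1,gene2,...
##   network: tf <TAB> target <TAB> role, role in {+, -, +-, ?}

readDataLines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  list(lines = lines[keep], lineno = keep)
}

splitGeneList <- function(s) {
  g <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  g[nzchar(g)]
}

#' Read an operon table
#'
#' Each data row is \code{operon_id<TAB>gene1,gene2,...} with genes listed in
#' transcription order. Gene order in the file is taken as transcription
#' order; strand resolution is assumed done upstream.
#'
#' @param path path to the operon TSV.
#' @return Named list of character vectors (genes in order), names are
#'   operon ids.
#' @seealso \code{\link{readAnnotation}}
#' @export
readOperons <- function(path) {
  d <- readDataLines(path)
  out <- list()
  seen <- character()
  for (k in seq_along(d$lines)) {
    f <- strsplit(d$lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop("operon file line ", d$lineno[k], ": expected 2 tab-separated fields")
    id <- trimws(f[1])
    if (id %in% names(out))
      stop("duplicate operon id '", id, "' (line ", d$lineno[k], ")")
    genes <- splitGeneList(f[2])
    if (!length(genes))
      stop("operon '", id, "' has an empty gene list (line ", d$lineno[k], ")")
    dup <- intersect(genes, seen)
    if (length(dup))
      stop("gene '", dup[1], "' listed in two operons (line ", d$lineno[k], ")")
    if (anyDuplicated(genes))
      stop("operon '", id, "' lists a gene twice (line ", d$lineno[k], ")")
    out[[id]] <- genes
    seen <- c(seen, genes)
  }
  out
}

#' Read a transcription-unit table
#'
#' Each data row is \code{tu_id<TAB>operon_id<TAB>gene1,gene2,...}. Every TU
#' must be a contiguous, order-consistent slice of its parent operon's gene
#' list; TUs may overlap and nest.
#'
#' @param path path to the TU TSV.
#' @param operons named list of operons as returned by
#'   \code{\link{readOperons}}.
#' @return Named list of character vectors with attribute \code{"operon"}
#'   (named character vector TU id -> operon id).
#' @export
readTUs <- function(path, operons) {
  d <- readDataLines(path)
  tus <- list()
  tuOperon <- character()
  for (k in seq_along(d$lines)) {
    f <- strsplit(d$lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("TU file line ", d$lineno[k], ": expected 3 tab-separated fields")
    id <- trimws(f[1]); op <- trimws(f[2])
    if (id %in% names(tus))
      stop("duplicate TU id '", id, "' (line ", d$lineno[k], ")")
    if (!op %in% names(operons))
      stop("TU '", id, "' references unknown operon '", op,
           "' (line ", d$lineno[k], ")")
    genes <- splitGeneList(f[3])
    err <- tuSliceError(genes, operons[[op]])
    if (!is.null(err))
      stop("TU '", id, "': ", err, " (line ", d$lineno[k], ")")
    tus[[id]] <- genes
    tuOperon[id] <- op
  }
  attr(tus, "operon") <- tuOperon
  tus
}

## NULL if genes form a contiguous order-consistent slice of operonGenes,
## otherwise a message.
tuSliceError <- function(genes, operonGenes) {
  if (!length(genes)) return("empty gene list")
  pos <- match(genes, operonGenes)
  if (anyNA(pos)) return(paste0("gene '", genes[which(is.na(pos))[1]],
                                "' not in the parent operon"))
  if (!identical(pos, seq(pos[1], length.out = length(pos))))
    return("genes are not a contiguous order-consistent slice of the operon")
  NULL
}

#' Read a regulatory-interaction network
#'
#' Each data row is \code{tf<TAB>target<TAB>role} with role one of \code{+}
#' (activation), \code{-} (repression), \code{+-} (dual), \code{?}
#' (unknown). Duplicate (tf, target) rows — typical of per-evidence exports —
#' are merged: identical roles deduplicate, activation and repression merge
#' to dual, dual absorbs any known role, and unknown yields to a known role.
#' The merge is order-independent.
#'
#' @param path path to the network TSV.
#' @return data.frame with columns \code{tf}, \code{target}, \code{role}
#'   (one row per (tf, target) pair).
#' @export
readNetwork <- function(path) {
  d <- readDataLines(path)
  if (!length(d$lines)) return(emptyInteractions())
  f <- strsplit(d$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3L))
    stop("network file line ", d$lineno[which(nf < 3L)[1]],
         ": expected 3 tab-separated fields")
  codes <- trimws(vapply(f, `[`, "", 3L))
  bad <- which(!codes %in% ROLE_CODES)
  if (length(bad))
    stop("network file line ", d$lineno[bad[1]],
         ": unrecognized role code '", codes[bad[1]], "'")
  df <- data.frame(tf = trimws(vapply(f, `[`, "", 1L)),
                   target = trimws(vapply(f, `[`, "", 2L)),
                   role = names(ROLE_CODES)[match(codes, ROLE_CODES)],
                   stringsAsFactors = FALSE)
  mergeInteractions(df)
}

#' Read a complete annotation from flat files
#'
#' Convenience wrapper combining \code{\link{readOperons}},
#' \code{\link{readTUs}} and \code{\link{readNetwork}} into a validated
#' \linkS4class{GenomeAnnotation}.
#'
#' @param operonsPath operon TSV path.
#' @param tuPath optional TU TSV path (operons without TUs get an implicit
#'   whole-operon TU downstream).
#' @param networkPath optional network TSV path.
#' @param check validate the assembled annotation (default TRUE).
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
readAnnotation <- function(operonsPath, tuPath = NULL, networkPath = NULL,
                           check = TRUE) {
  ops <- readOperons(operonsPath)
  tus <- list(); tuOperon <- character()
  if (!is.null(tuPath)) {
    tus <- readTUs(tuPath, ops)
    tuOperon <- attr(tus, "operon")
    attr(tus, "operon") <- NULL
  }
  net <- if (is.null(networkPath)) emptyInteractions() else readNetwork(networkPath)
  GenomeAnnotation(operons = ops, tus = tus, tuOperon = tuOperon,
                   interactions = net, check = check)
}

#' Write an annotation back to flat files
#'
#' Serializes in the same dialect the readers accept, so that
#' write-then-read round-trips to an identical annotation.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param operonsPath,tuPath,networkPath output paths (each optional except
#'   the operon table).
#' @return Invisibly, the annotation.
#' @export
writeAnnotation <- function(annotation, operonsPath, tuPath = NULL,
                            networkPath = NULL) {
  writeLines(paste0(names(annotation@operons), "\t",
                    vapply(annotation@operons, paste, "", collapse = ",")),
             operonsPath)
  if (!is.null(tuPath))
    writeLines(paste0(names(annotation@tus), "\t",
                      annotation@tuOperon[names(annotation@tus)], "\t",
                      vapply(annotation@tus, paste, "", collapse = ",")),
               tuPath)
  if (!is.null(networkPath)) {
    net <- annotation@interactions
    writeLines(paste0(net$tf, "\t", net$target, "\t", ROLE_CODES[net$role]),
               networkPath)
  }
  invisible(annotation)
}

#' Audit an annotation against its structural invariants
#'
#' Report-only validation: returns every violation found rather than
#' stopping at the first. Checked invariants: unique, whitespace-free gene
#' and operon ids; each gene in at most one operon; no duplicate genes
#' within an operon; every TU resolves to an operon and is a contiguous
#' order-consistent slice of it; interaction roles are from the four-level
#' vocabulary and (tf, target) pairs are unique. Cross-references between
#' the network and the operon map (genes present in one but not the other)
#' are reported as notes, not violations.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return A list with elements \code{violations} and \code{notes}
#'   (character vectors; an empty \code{violations} means valid).
#' @examples
#' ann <- GenomeAnnotation(operons = list(op1 = c("a", "b")))
#' validateAnnotation(ann)$violations   # character(0)
#' @export
validateAnnotation <- function(annotation) {
  v <- character(); notes <- character()
  ops <- annotation@operons
  opGenes <- unlist(ops, use.names = FALSE)

  badId <- function(ids) ids[!nzchar(ids) | grepl("[[:space:]]", ids)]
  b <- badId(opGenes)
  if (length(b))
    v <- c(v, paste0("invalid gene id '", unique(b), "'"))
  if (length(ops)) {
    if (is.null(names(ops)) || any(!nzchar(names(ops))))
      v <- c(v, "operons must have non-empty ids")
    if (anyDuplicated(names(ops)))
      v <- c(v, paste0("duplicate operon id '",
                       unique(names(ops)[duplicated(names(ops))]), "'"))
    if (any(lengths(ops) == 0L))
      v <- c(v, paste0("operon '", names(ops)[lengths(ops) == 0L],
                       "' has no genes"))
    within <- unlist(lapply(ops, function(g) g[duplicated(g)]),
                     use.names = FALSE)
    if (length(within))
      v <- c(v, paste0("gene '", unique(within),
                       "' duplicated within an operon"))
    # partition property across operons (ignore within-operon duplicates,
    # already reported)
    once <- lapply(ops, unique)
    all1 <- unlist(once, use.names = FALSE)
    cross <- unique(all1[duplicated(all1)])
    if (length(cross))
      v <- c(v, paste0("gene '", cross, "' appears in two operons"))
  }

  for (id in names(annotation@tus)) {
    op <- annotation@tuOperon[[id]]
    if (!op %in% names(ops)) {
      v <- c(v, paste0("TU '", id, "' references unknown operon '", op, "'"))
      next
    }
    err <- tuSliceError(annotation@tus[[id]], ops[[op]])
    if (!is.null(err)) v <- c(v, paste0("TU '", id, "': ", err))
  }

  net <- annotation@interactions
  if (nrow(net)) {
    badRole <- unique(net$role[!net$role %in% ROLE_LEVELS])
    if (length(badRole))
      v <- c(v, paste0("unknown interaction role '", badRole, "'"))
    key <- paste(net$tf, net$target, sep = "\r")
    if (anyDuplicated(key))
      v <- c(v, "multiple interactions stored for one (tf, target) pair")
    netGenes <- unique(c(net$tf, net$target))
    orphan <- setdiff(netGenes, opGenes)
    if (length(orphan))
      notes <- c(notes, paste0(length(orphan),
                               " network gene(s) absent from any operon"))
    unreg <- setdiff(opGenes, netGenes)
    if (length(unreg))
      notes <- c(notes, paste0(length(unreg),
                               " operon gene(s) absent from the network"))
  }
  list(violations = v, notes = notes)
}
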