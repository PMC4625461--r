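## Internal helpers.

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Merge the roles observed for one (tf, target) pair into a single role.
## Identical roles deduplicate; activation + repression = dual; dual absorbs
## any known role; unknown yields to any known role.
mergeRoles <- function(roles) {
  known <- setdiff(unique(roles), "unknown")
  if (!length(known)) return("unknown")
  if ("dual" %in% known || all(c("activation", "repression") %in% known))
    return("dual")
  known
}

## Collapse duplicate (tf, target) rows of an interaction table via mergeRoles.
mergeInteractions <- function(df) {
  if (!nrow(df)) return(emptyInteractions())
  key <- paste(df$tf, df$target, sep = "\r")
  if (!anyDuplicated(key)) {
    rownames(df) <- NULL
    return(df[c("tf", "target", "role")])
  }
  idx <- split(seq_len(nrow(df)), key)
  # preserve first-appearance order of pairs
  idx <- idx[order(vapply(idx, min, 0L))]
  out <- data.frame(
    tf = vapply(idx, function(i) df$tf[i[1]], ""),
    target = vapply(idx, function(i) df$target[i[1]], ""),
    role = vapply(idx, function(i) mergeRoles(df$role[i]), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## TU member lists of one operon, adding the implicit whole-operon TU when
## the operon has no listed TU.
effectiveTUs <- function(annotation, operonId) {
  ids <- names(annotation@tuOperon)[annotation@tuOperon == operonId]
  if (!length(ids)) {
    tu <- list(annotation@operons[[operonId]])
    names(tu) <- paste0(operonId, ".whole")
    return(tu)
  }
  annotation@tus[ids]
}
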