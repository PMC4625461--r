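## Shared fixtures and independent brute-force oracles. The oracles follow
## different algorithmic routes than the package (exhaustive enumeration,
## pairwise comparison) so that agreement is meaningful.

## Operon bcsABZC with its two promoters: the classic nested-TU example.
fig1Annotation <- function() {
  GenomeAnnotation(
    operons = list(bcsABZC = c("bcsA", "bcsB", "bcsZ", "bcsC")),
    tus = list(bcsABZC = c("bcsA", "bcsB", "bcsZ", "bcsC"),
               bcsBZ = c("bcsB", "bcsZ")),
    tuOperon = c(bcsABZC = "bcsABZC", bcsBZ = "bcsABZC"))
}

## Fur regulon toy: sucA/sucD activated and sucB/sucC repressed by Fur,
## all four sharing regulators CRP, ArcA, IHF, Fur, FNR; cyoB and entD are
## additional Fur-repressed genes.
fig2Annotation <- function() {
  suc <- c("sucA", "sucD", "sucB", "sucC")
  rows <- rbind(
    data.frame(tf = "Fur", target = c("sucA", "sucD"), role = "activation"),
    data.frame(tf = "Fur", target = c("cyoB", "sucB", "sucC", "entD"),
               role = "repression"),
    expand.grid(tf = c("CRP", "ArcA", "IHF", "FNR"), target = suc,
                role = "activation", stringsAsFactors = FALSE))
  ops <- c(list(sucOp = suc),
           as.list(setNames(c("cyoB", "entD", "CRP", "ArcA", "IHF", "Fur",
                              "FNR"),
                            c("cyoOp", "entOp", "crpOp", "arcOp", "ihfOp",
                              "furOp", "fnrOp"))))
  GenomeAnnotation(operons = ops,
                   interactions = rows[c("tf", "target", "role")])
}

## Small random annotation, drawn independently of the package's simulator:
## arbitrary contiguous TU slices (not only suffixes) and per-gene TF
## targets. Always valid by construction.
randomSmallAnnotation <- function(seed, maxOperons = 6, maxGenes = 5,
                                  maxTUs = 4, maxTFs = 5) {
  set.seed(seed)
  nOp <- sample(maxOperons, 1)
  operons <- list()
  tus <- list()
  tuOperon <- character()
  g <- 0L
  for (o in seq_len(nOp)) {
    n <- sample(maxGenes, 1)
    genes <- paste0("g", g + seq_len(n)); g <- g + n
    op <- paste0("op", o)
    operons[[op]] <- genes
    for (t in seq_len(sample(0:maxTUs, 1))) {
      i <- sample(n, 1)
      j <- if (i == n) n else sample(i:n, 1)
      id <- paste0(op, ".t", t)
      tus[[id]] <- genes[i:j]
      tuOperon[id] <- op
    }
  }
  allGenes <- unlist(operons, use.names = FALSE)
  net <- emptyNet()
  nTF <- sample(0:maxTFs, 1)
  if (nTF > 0) {
    for (t in seq_len(nTF)) {
      k <- sample(length(allGenes), 1)
      net <- rbind(net, data.frame(
        tf = paste0("T", t), target = sample(allGenes, k),
        role = sample(c("activation", "repression", "dual", "unknown"),
                      k, replace = TRUE),
        stringsAsFactors = FALSE))
    }
  }
  GenomeAnnotation(operons = operons, tus = tus, tuOperon = tuOperon,
                   interactions = net)
}

emptyNet <- function() {
  data.frame(tf = character(), target = character(), role = character(),
             stringsAsFactors = FALSE)
}

## COPR oracle: enumerate all 2^(n-1) segmentations of each operon into
## contiguous blocks, keep those in which no TU starts or ends strictly
## inside a block, and return the coarsest (fewest cuts) valid one.
bruteCOPR <- function(annotation) {
  out <- list()
  for (op in names(operons(annotation))) {
    genes <- operons(annotation)[[op]]
    n <- length(genes)
    tuIds <- names(attr(transcriptionUnits(annotation), "operon"))[
      attr(transcriptionUnits(annotation), "operon") == op]
    tuList <- if (length(tuIds)) transcriptionUnits(annotation)[tuIds]
              else list(genes)
    best <- NULL
    for (mask in 0:(2^(max(n - 1, 0)) - 1)) {
      cuts <- which(bitwAnd(mask, 2^(seq_len(max(n - 1, 0)) - 1)) > 0)
      ok <- TRUE
      for (tu in tuList) {
        i <- match(tu[1], genes); j <- match(tu[length(tu)], genes)
        startB <- i - 1; endB <- j          # boundary indices in 1..n-1
        if (startB >= 1 && !(startB %in% cuts)) ok <- FALSE
        if (endB <= n - 1 && !(endB %in% cuts)) ok <- FALSE
        if (!ok) break
      }
      if (ok && (is.null(best) || length(cuts) < length(best))) best <- cuts
    }
    blockId <- cumsum(c(1, as.integer(seq_len(max(n - 1, 0)) %in% best)))
    for (k in unique(blockId))
      out[[paste0(op, ".", k)]] <- genes[blockId == k]
  }
  out
}

## Regulon oracle: O(n^2) pairwise comparison of explicitly collected
## regulator sets (or (tf, role) pair sets when strict).
bruteRegulons <- function(annotation, strict = FALSE) {
  net <- interactions(annotation)
  genes <- unique(net$target)
  keyOf <- function(g) {
    sub <- net[net$target == g, , drop = FALSE]
    if (strict) sort(paste(sub$tf, sub$role)) else sort(unique(sub$tf))
  }
  keys <- lapply(setNames(genes, genes), keyOf)
  groups <- list()
  for (g in genes) {
    placed <- FALSE
    for (i in seq_along(groups)) {
      if (identical(keys[[groups[[i]][1]]], keys[[g]])) {
        groups[[i]] <- c(groups[[i]], g); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- g
  }
  groups
}

## One-sided paired Wilcoxon oracle: full enumeration of all 2^n sign
## assignments of the non-zero differences.
bruteWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Wnull <- apply(signs, 1, function(s) sum(r[s]))
  mean(Wnull >= W)
}

## Same partition regardless of naming/order?
samePartition <- function(a, b) {
  norm <- function(x) {
    x <- lapply(x, function(s) sort(unclass(s)))
    x[order(vapply(x, `[`, "", 1))]
  }
  identical(unname(norm(a)), unname(norm(b)))
}

## Tiny labelled expression series from a matrix.
makeSeries <- function(values, labels, id = "s") {
  ExpressionSeries(values, labels, seriesId = id)
}

## Random two-class noise series: nGenes x (2 * perClass).
noiseSeries <- function(nGenes, perClass, seed, id = "noise") {
  set.seed(seed)
  n <- 2L * perClass
  m <- matrix(rnorm(nGenes * n), nrow = nGenes,
              dimnames = list(paste0("g", seq_len(nGenes)),
                              paste0("s", seq_len(n))))
  makeSeries(m, setNames(rep(c("a", "b"), each = perClass), colnames(m)),
             id = id)
}

## Noise series with k phenotype classes, perClass samples each.
multiClassSeries <- function(k, perClass, seed, id = paste0("ser", seed),
                             nGenes = 10) {
  set.seed(seed)
  n <- k * perClass
  m <- matrix(rnorm(nGenes * n), nrow = nGenes,
              dimnames = list(paste0("g", seq_len(nGenes)),
                              paste0(id, "_s", seq_len(n))))
  lab <- setNames(rep(paste0(id, "_c", seq_len(k)), each = perClass),
                  colnames(m))
  makeSeries(m, lab, id = id)
}
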