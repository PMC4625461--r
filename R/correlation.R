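## Within-set expression-correlation study: combinatorially weighted set
## sampling, random-pair baseline, histogram/summary of coefficients.

corMethodFun <- function(method) {
  function(x, y) suppressWarnings(cor(x, y, method = method))
}

#' Sample within-set gene-pair correlations
#'
#' Iterates \code{nIter} times: (i) draw a gene set of the family with
#' probability proportional to the number of 2-combinations of its size,
#' counting measured members only; (ii) draw a pair of two distinct genes
#' uniformly from that set; (iii) compute the correlation of their
#' expression across all samples. Single-gene sets are omitted. Pairs
#' involving a zero-variance gene have no defined correlation and are
#' rejected and redrawn (the rejection count is returned as an attribute).
#'
#' @param family a \linkS4class{GeneSetFamily}.
#' @param expr an \linkS4class{ExpressionSeries}.
#' @param nIter number of sampled pairs (the protocol uses 5000).
#' @param seed integer seed.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return data.frame with columns \code{set}, \code{geneA}, \code{geneB},
#'   \code{r}, one row per draw; attribute \code{"rejected"} counts redraws.
#' @export
sampleWithinFamily <- function(family, expr, nIter = 5000L, seed = 1L,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vals <- exprValues(expr)
  measured <- lapply(family@sets, intersect, rownames(vals))
  eligible <- measured[lengths(measured) >= 2L]
  if (!length(eligible))
    stop("no set has at least two measured members")
  w <- choose(lengths(eligible), 2)
  corFun <- corMethodFun(method)
  withSeed(seed, {
    pick <- sample(length(eligible), nIter, replace = TRUE, prob = w)
    setNm <- geneA <- geneB <- character(nIter)
    r <- numeric(nIter)
    rejected <- 0L
    for (k in seq_len(nIter)) {
      repeat {
        i <- pick[k]
        pair <- sample(eligible[[i]], 2L)
        rr <- corFun(vals[pair[1L], ], vals[pair[2L], ])
        if (is.finite(rr)) break
        rejected <- rejected + 1L
        i <- pick[k] <- sample(length(eligible), 1L, prob = w)
      }
      setNm[k] <- names(eligible)[i]
      geneA[k] <- pair[1L]; geneB[k] <- pair[2L]
      r[k] <- rr
    }
    out <- data.frame(set = setNm, geneA = geneA, geneB = geneB, r = r,
                      stringsAsFactors = FALSE)
    attr(out, "rejected") <- rejected
    out
  })
}

#' Sample random gene-pair correlations
#'
#' Baseline for \code{\link{sampleWithinFamily}}: \code{nIter} unordered
#' pairs of distinct genes drawn uniformly from the full measured gene
#' list, not bound to any gene set. Zero-variance pairs are rejected and
#' redrawn.
#'
#' @inheritParams sampleWithinFamily
#' @return data.frame as in \code{\link{sampleWithinFamily}} with
#'   \code{set = "random"}.
#' @export
sampleRandomPairs <- function(expr, nIter = 5000L, seed = 1L,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vals <- exprValues(expr)
  if (nrow(vals) < 2L) stop("need at least two measured genes")
  corFun <- corMethodFun(method)
  genes <- rownames(vals)
  withSeed(seed, {
    geneA <- geneB <- character(nIter)
    r <- numeric(nIter)
    rejected <- 0L
    for (k in seq_len(nIter)) {
      repeat {
        pair <- sample(genes, 2L)
        rr <- corFun(vals[pair[1L], ], vals[pair[2L], ])
        if (is.finite(rr)) break
        rejected <- rejected + 1L
      }
      geneA[k] <- pair[1L]; geneB[k] <- pair[2L]
      r[k] <- rr
    }
    out <- data.frame(set = "random", geneA = geneA, geneB = geneB, r = r,
                      stringsAsFactors = FALSE)
    attr(out, "rejected") <- rejected
    out
  })
}

#' Histogram and summary of sampled correlations
#'
#' Bins the sampled coefficients over [-1, 1] and reports location
#' summaries, the tabular counterpart of the correlation density plots.
#'
#' @param samples data.frame from one of the samplers (or a numeric vector
#'   of coefficients).
#' @param bins number of equal-width bins over [-1, 1].
#' @return A list with \code{histogram} (data.frame: \code{binLeft},
#'   \code{binRight}, \code{count}, \code{density}), \code{mean},
#'   \code{median} and \code{fracPositive}.
#' @export
correlationSummary <- function(samples, bins = 40L) {
  r <- if (is.data.frame(samples)) samples$r else as.numeric(samples)
  if (!length(r)) stop("no correlation samples")
  breaks <- seq(-1, 1, length.out = bins + 1L)
  idx <- findInterval(r, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  count <- tabulate(idx, nbins = bins)
  width <- diff(breaks)
  list(histogram = data.frame(binLeft = breaks[-(bins + 1L)],
                              binRight = breaks[-1L],
                              count = count,
                              density = count / (length(r) * width)),
       mean = mean(r), median = median(r), fracPositive = mean(r > 0))
}
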