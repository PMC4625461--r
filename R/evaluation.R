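## Experimental protocol: binary-dataset pool construction, LOOCV-SVM
## accuracy, Friedman rank sums, and win/tie/loss + one-sided paired
## Wilcoxon method comparisons.

#' Build the pool of binary-class datasets
#'
#' For each expression series and each unordered pair of its phenotype
#' classes, combines the samples of those two classes into a binary-class
#' dataset (which an SVM can natively process) and adds it to the pool. A
#' series with c classes contributes choose(c, 2) datasets; series with
#' fewer than two classes are skipped with a warning.
#'
#' @param series an \linkS4class{ExpressionSeries} or a list of them.
#' @return A list of binary \linkS4class{ExpressionSeries}; each carries its
#'   source series id and its class pair in \code{metadata} (see
#'   \code{\link{classPair}}).
#' @export
buildPool <- function(series) {
  if (is(series, "ExpressionSeries")) series <- list(series)
  pool <- list()
  for (se in series) {
    classes <- sort(unique(sampleLabels(se)))
    if (length(classes) < 2L) {
      warning("series '", seriesId(se), "' has fewer than 2 classes, skipped")
      next
    }
    for (a in seq_len(length(classes) - 1L)) {
      for (b in seq(a + 1L, length(classes))) {
        pair <- c(classes[a], classes[b])
        ds <- se[, sampleLabels(se) %in% pair]
        S4Vectors::metadata(ds)$classPair <- pair
        pool[[length(pool) + 1L]] <- ds
      }
    }
  }
  pool
}

## phenotype classes qualified by their source series (class labels from
## different series never coincide)
qualifiedClasses <- function(ds) paste(seriesId(ds), classPair(ds), sep = "::")
datasetId <- function(ds) paste(c(seriesId(ds), classPair(ds)), collapse = "::")

#' Select mutually class-disjoint testing datasets
#'
#' Greedy seeded selection of testing datasets from the pool: the first
#' dataset is drawn at random, then datasets sharing no phenotype class
#' (and therefore no sample) with those already included are repeatedly
#' added at random until none remain. The result is pairwise class-disjoint
#' and maximal under the greedy rule.
#'
#' @param pool list of binary datasets from \code{\link{buildPool}}.
#' @param seed integer seed for the draw order.
#' @return A sub-list of \code{pool}.
#' @export
selectTesting <- function(pool, seed = 1L) {
  if (!length(pool)) stop("empty pool")
  ord <- withSeed(seed, sample(length(pool)))
  chosen <- integer()
  used <- character()
  for (i in ord) {
    cls <- qualifiedClasses(pool[[i]])
    if (!any(cls %in% used)) {
      chosen <- c(chosen, i)
      used <- c(used, cls)
    }
  }
  pool[chosen]
}

#' Draw selection datasets disjoint from the testing collection
#'
#' Draws up to n datasets uniformly at random (without replacement) from
#' the pool members that are not themselves testing datasets. Selection
#' datasets may share classes with one another; they are used only to pick
#' the best-performing gene-set subtype before the independent testing
#' comparisons.
#'
#' @param pool list of binary datasets.
#' @param testing datasets to exclude (by source series + class pair).
#' @param n number of draws.
#' @param seed integer seed.
#' @return A sub-list of \code{pool} of length \code{min(n, available)};
#'   warns when fewer than n are available.
#' @export
selectSelection <- function(pool, testing, n, seed = 1L) {
  excluded <- vapply(testing, datasetId, "")
  avail <- which(!vapply(pool, datasetId, "") %in% excluded)
  if (n > length(avail)) {
    warning("only ", length(avail), " dataset(s) available, returning all")
    n <- length(avail)
  }
  if (n == 0L) return(list())
  pool[withSeed(seed, sample(avail, n))]
}

#' SVM classifier configuration
#'
#' Defaults: soft-margin linear SVM with cost 1 and features standardized
#' on the training fold only — the standard configuration for
#' few-samples/many-features expression classification. A radial kernel
#' (gamma defaulting to 1/#features) is available but degenerates to
#' majority voting when thousands of mostly uninformative standardized
#' features make pairwise distances concentrate, which is exactly the
#' regime of these datasets.
#'
#' @param kernel e1071 kernel name (\code{"linear"} default).
#' @param cost soft-margin cost C.
#' @param gamma kernel width for non-linear kernels; \code{NULL} means
#'   1/#features.
#' @param standardize center/scale features using training-fold statistics.
#' @return A list understood by \code{\link{loocvAccuracy}}.
#' @export
svmConfig <- function(kernel = "linear", cost = 1, gamma = NULL,
                      standardize = TRUE) {
  list(kernel = kernel, cost = cost, gamma = gamma,
       standardize = standardize)
}

#' Leave-one-out cross-validated classification accuracy
#'
#' For each sample: an SVM is trained on the remaining samples (feature
#' standardization fitted on the training portion only) and the held-out
#' sample is predicted; the accuracy is the fraction of correct
#' predictions. A degenerate training fold containing a single class
#' predicts that (majority) class.
#'
#' @param features a \linkS4class{FeatureMatrix} or a features-by-samples
#'   numeric matrix.
#' @param labels binary class labels, named by sample or aligned with the
#'   feature columns.
#' @param config classifier configuration from \code{\link{svmConfig}}.
#' @return Accuracy in [0, 1].
#' @export
loocvAccuracy <- function(features, labels, config = svmConfig()) {
  x <- if (is(features, "FeatureMatrix")) featureValues(features) else features
  if (!is.null(names(labels)) && !is.null(colnames(x)))
    labels <- labels[colnames(x)]
  labels <- as.character(labels)
  ns <- ncol(x)
  stopifnot(length(labels) == ns)
  if (min(table(labels)) < 2L)
    stop("need at least 2 samples per class for LOOCV")
  gamma <- config$gamma %||% (1 / nrow(x))
  correct <- logical(ns)
  for (i in seq_len(ns)) {
    trainX <- x[, -i, drop = FALSE]
    trainY <- labels[-i]
    testX <- x[, i, drop = FALSE]
    if (config$standardize) {
      mu <- rowMeans(trainX)
      sdv <- apply(trainX, 1L, sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      trainX <- (trainX - mu) / sdv
      testX <- (testX - mu) / sdv
    }
    if (length(unique(trainY)) < 2L) {
      pred <- trainY[1L]
    } else {
      fit <- e1071::svm(x = t(trainX), y = factor(trainY),
                        type = "C-classification", kernel = config$kernel,
                        cost = config$cost, gamma = gamma, scale = FALSE)
      pred <- as.character(predict(fit, t(testX)))
    }
    correct[i] <- pred == labels[i]
  }
  mean(correct)
}

#' Friedman rank sums over an accuracy table
#'
#' Within each dataset, the methods are ranked by accuracy with the best
#' method receiving the highest rank (m for m methods); ties get mid-ranks.
#' The per-method rank sums are the selection criterion (higher is better);
#' the Friedman chi-square statistic tests the null of equal performance.
#'
#' @param acc numeric matrix of accuracies, methods in rows (rownames),
#'   datasets in columns.
#' @return A list with \code{rankSums} (named), \code{statistic},
#'   \code{df} and \code{pValue}. The rank sums always total
#'   \code{ncol(acc) * m * (m + 1) / 2}.
#' @export
friedmanRanks <- function(acc) {
  acc <- as.matrix(acc)
  m <- nrow(acc); n <- ncol(acc)
  if (m < 2L || n < 2L) stop("need at least 2 methods and 2 datasets")
  ranks <- apply(acc, 2L, rank)          # m x n, highest accuracy -> rank m
  rankSums <- rowSums(ranks)
  ## chi-square with the standard tie correction (reduces to the classical
  ## statistic when no dataset has tied accuracies)
  tieCorr <- sum(apply(acc, 2L, function(col) {
    t <- table(col); sum(t^3 - t)
  }))
  denom <- n * m * (m + 1) - tieCorr / (m - 1)
  stat <- 12 * sum((rankSums - n * (m + 1) / 2)^2) / denom
  df <- m - 1
  list(rankSums = rankSums, statistic = stat, df = df,
       pValue = pchisq(stat, df, lower.tail = FALSE))
}

#' Compare two methods across datasets
#'
#' Counts per-dataset wins, ties and losses of method A against method B
#' (a tie is exact accuracy equality) and computes the one-sided paired
#' Wilcoxon signed-rank p-value for the alternative "A is better than B".
#' Zero differences are dropped (Pratt handling of zeros is available); the
#' exact tie-aware null distribution is enumerated for at most
#' \code{exactLimit} non-zero pairs, beyond that a normal approximation
#' with tie correction and continuity correction is used. If all pairs are
#' tied the result is flagged \code{"same"} with p = 1.
#'
#' @param accA,accB equal-length paired per-dataset accuracy vectors.
#' @param zeros \code{"drop"} (default) or \code{"pratt"}.
#' @param exactLimit maximum number of non-zero pairs for exact enumeration.
#' @return A list with \code{wins}, \code{ties}, \code{losses},
#'   \code{pValue} and \code{direction} (\code{"A"}, \code{"B"} or
#'   \code{"same"}).
#' @export
compareMethods <- function(accA, accB, zeros = c("drop", "pratt"),
                           exactLimit = 25L) {
  zeros <- match.arg(zeros)
  stopifnot(length(accA) == length(accB))
  d <- accA - accB
  wins <- sum(d > 0); losses <- sum(d < 0); ties <- sum(d == 0)
  if (wins + losses == 0L)
    return(list(wins = wins, ties = ties, losses = losses, pValue = 1,
                direction = "same"))
  if (zeros == "drop") {
    dd <- d[d != 0]
    r <- rank(abs(dd))
  } else {
    r <- rank(abs(d))[d != 0]            # Pratt: rank with zeros, then drop
    dd <- d[d != 0]
  }
  W <- sum(r[dd > 0])
  n <- length(dd)
  if (n <= exactLimit) {
    p <- signedRankExactP(r, W)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  }
  direction <- if (wins > losses) "A" else if (losses > wins) "B" else "A"
  list(wins = wins, ties = ties, losses = losses, pValue = p,
       direction = direction)
}

## Exact one-sided P(W >= w) for the signed-rank statistic with arbitrary
## (possibly tied, mid-) ranks r: subset-sum distribution over all 2^n sign
## assignments, computed by polynomial convolution on doubled ranks.
signedRankExactP <- function(r, W) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (rr in r2) {
    g <- f
    g[(rr + 1L):(total + 1L)] <- g[(rr + 1L):(total + 1L)] +
      f[1L:(total + 1L - rr)]
    f <- g
  }
  W2 <- as.integer(round(2 * W))
  sum(f[(W2 + 1L):(total + 1L)]) / 2^length(r2)
}
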