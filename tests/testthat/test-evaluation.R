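test_that("pool construction yields one dataset per class pair", {
  se3 <- multiClassSeries(3, 3, seed = 1)
  pool <- buildPool(se3)
  expect_length(pool, 3L)   # choose(3, 2)
  pairs <- lapply(pool, classPair)
  expect_identical(anyDuplicated(pairs), 0L)
  for (ds in pool) {
    expect_identical(length(unique(sampleLabels(ds))), 2L)
    expect_identical(ncol(ds), 6L)
  }

  # unequal class sizes combine all their samples
  m <- matrix(rnorm(18), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:9)))
  se <- makeSeries(m, setNames(rep(c("A", "B"), c(4, 5)), colnames(m)))
  expect_identical(ncol(buildPool(se)[[1]]), 9L)

  expect_warning(out <- buildPool(makeSeries(
    m, setNames(rep("A", 9), colnames(m)))), "fewer than 2")
  expect_length(out, 0L)

  # pool size adds binomial coefficients over series
  pool2 <- buildPool(list(multiClassSeries(4, 2, seed = 2),
                          multiClassSeries(2, 2, seed = 3)))
  expect_length(pool2, choose(4, 2) + choose(2, 2))
})

test_that("testing selection is pairwise class-disjoint and greedy-maximal", {
  # all pairs of one 3-class series share a class: exactly one survives
  pool <- buildPool(multiClassSeries(3, 3, seed = 4))
  for (seed in 1:5) expect_length(selectTesting(pool, seed = seed), 1L)

  # mutually disjoint datasets are all selected
  disjoint <- buildPool(list(multiClassSeries(2, 2, seed = 5, id = "a"),
                             multiClassSeries(2, 2, seed = 6, id = "b")))
  expect_length(selectTesting(disjoint, seed = 1), 2L)

  # property over random multi-series pools
  for (seed in 1:10) {
    set.seed(seed)
    series <- lapply(seq_len(3), function(i)
      multiClassSeries(sample(2:5, 1), 2, seed = 100 * seed + i,
                       id = paste0("ser", seed, "_", i)))
    pool <- buildPool(series)
    sel <- selectTesting(pool, seed = seed)
    key <- function(ds) paste(seriesId(ds), classPair(ds), sep = "::")
    used <- unlist(lapply(sel, key))
    expect_identical(anyDuplicated(used), 0L)     # pairwise disjoint
    selIds <- vapply(sel, function(d) paste(key(d), collapse = "|"), "")
    for (ds in pool) {                            # greedy-maximal
      if (paste(key(ds), collapse = "|") %in% selIds) next
      expect_true(any(key(ds) %in% used))
    }
  }
})

test_that("selection datasets are disjoint from testing and reproducible", {
  pool <- buildPool(list(multiClassSeries(4, 2, seed = 7, id = "a"),
                         multiClassSeries(3, 2, seed = 8, id = "b")))
  testing <- selectTesting(pool, seed = 2)
  sel <- selectSelection(pool, testing, n = 3, seed = 9)
  expect_length(sel, 3L)
  id <- function(d) paste(c(seriesId(d), classPair(d)), collapse = "::")
  expect_length(intersect(vapply(sel, id, ""), vapply(testing, id, "")), 0L)
  expect_identical(vapply(selectSelection(pool, testing, 3, seed = 9), id, ""),
                   vapply(sel, id, ""))

  expect_length(selectSelection(pool, testing, 0, seed = 1), 0L)
  expect_warning(all <- selectSelection(pool, pool, 5, seed = 1), "available")
  expect_length(all, 0L)
  expect_warning(sel2 <- selectSelection(pool, testing, 1000, seed = 1),
                 "available")
  expect_length(sel2, length(pool) - length(testing))
})

test_that("LOOCV is perfect on separated clusters and order-invariant", {
  set.seed(3)
  x <- matrix(c(rnorm(9, -4), rnorm(9, 4)), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  lab <- setNames(rep(c("lo", "hi"), each = 3), colnames(x))
  expect_identical(loocvAccuracy(x, lab), 1)

  set.seed(4)
  x2 <- matrix(rnorm(48), nrow = 6,
               dimnames = list(paste0("f", 1:6), paste0("s", 1:8)))
  x2[1, ] <- c(rnorm(4, -1.5), rnorm(4, 1.5))
  lab2 <- setNames(rep(c("a", "b"), each = 4), colnames(x2))
  acc <- loocvAccuracy(x2, lab2)
  sPerm <- sample(colnames(x2)); fPerm <- sample(rownames(x2))
  expect_identical(loocvAccuracy(x2[fPerm, sPerm], lab2[sPerm]), acc)

  expect_error(loocvAccuracy(x2, setNames(rep(c("a", "b"), c(7, 1)),
                                          colnames(x2))),
               "at least 2 samples")
})

test_that("Friedman ranking rewards the best method and respects rank-sum totals", {
  acc <- rbind(best = c(0.9, 0.8, 0.95), mid = c(0.5, 0.6, 0.7),
               worst = c(0.1, 0.2, 0.3))
  fr <- friedmanRanks(acc)
  expect_identical(unname(fr$rankSums["best"]), 9)    # m * n_datasets
  expect_identical(unname(fr$rankSums["worst"]), 3)

  tied <- matrix(0.5, nrow = 4, ncol = 6,
                 dimnames = list(paste0("m", 1:4), NULL))
  expect_true(all(friedmanRanks(tied)$rankSums == 6 * (4 + 1) / 2))

  for (seed in 1:10) {
    set.seed(seed)
    m <- sample(2:6, 1); n <- sample(2:30, 1)
    a <- matrix(sample(seq(0, 1, 0.125), m * n, replace = TRUE), nrow = m,
                dimnames = list(paste0("meth", 1:m), NULL))
    expect_equal(sum(friedmanRanks(a)$rankSums), n * m * (m + 1) / 2)
  }
})

test_that("Friedman statistic matches stats::friedman.test without ties", {
  set.seed(11)
  acc <- matrix(rnorm(5 * 12), nrow = 5,
                dimnames = list(paste0("m", 1:5), NULL))
  fr <- friedmanRanks(acc)
  ref <- stats::friedman.test(t(acc))
  expect_equal(fr$statistic, unname(ref$statistic))
  expect_equal(fr$pValue, unname(ref$p.value))
})

test_that("paired Wilcoxon: five uniform wins give the exact p of 1/32", {
  a <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  res <- compareMethods(a, a - 0.1)
  expect_identical(res$wins, 5L)
  expect_identical(res$losses, 0L)
  expect_equal(res$pValue, 1 / 32)
  expect_identical(res$direction, "A")
})

test_that("identical accuracy vectors are flagged same with p = 1", {
  v <- c(0.5, 0.75, 1)
  res <- compareMethods(v, v)
  expect_identical(res$wins, 0L)
  expect_identical(res$losses, 0L)
  expect_identical(res$ties, 3L)
  expect_identical(res$pValue, 1)
  expect_identical(res$direction, "same")
})

test_that("exact Wilcoxon p equals full sign-flip enumeration (with ties and zeros)", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    # accuracies on a 1/8 grid produce tied |differences| and zeros
    a <- sample(seq(0, 1, 0.125), n, replace = TRUE)
    b <- sample(seq(0, 1, 0.125), n, replace = TRUE)
    if (all(a == b)) next
    res <- compareMethods(a, b)
    expect_equal(res$pValue, bruteWilcoxonP(a - b), info = rep)
    expect_identical(res$wins + res$ties + res$losses, as.integer(n))
    # antisymmetry of the counts
    swap <- compareMethods(b, a)
    expect_identical(swap$wins, res$losses)
    expect_identical(swap$losses, res$wins)
    expect_equal(swap$pValue, bruteWilcoxonP(b - a))
  }
})

test_that("exact Wilcoxon p matches stats::wilcox.test when tie-free", {
  set.seed(31)
  for (rep in 1:10) {
    d <- rnorm(sample(4:12, 1))
    a <- 0.5 + d / 10; b <- rep(0.5, length(d))
    res <- compareMethods(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                              exact = TRUE)
    expect_equal(res$pValue, unname(ref$p.value))
  }
})

test_that("large-sample Wilcoxon approximation is close to the exact value", {
  set.seed(41)
  d <- rnorm(30, mean = 0.3)
  a <- 0.5 + d / 10; b <- rep(0.5, 30)
  exact <- compareMethods(a, b, exactLimit = 40L)$pValue
  approx <- compareMethods(a, b, exactLimit = 10L)$pValue
  expect_lt(abs(exact - approx) / exact, 0.25)
  # Pratt handling runs and stays a valid probability
  p <- compareMethods(a, b, zeros = "pratt")$pValue
  expect_true(p > 0 && p <= 1)
})
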