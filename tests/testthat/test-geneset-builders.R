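test_that("OPR/TU builders reproduce the nested-promoter example", {
  ann <- fig1Annotation()
  opr <- buildOPR(ann)
  expect_identical(geneSets(opr),
                   list(bcsABZC = c("bcsA", "bcsB", "bcsZ", "bcsC")))

  tu <- buildTU(ann)
  expect_setequal(lapply(unname(geneSets(tu)), sort),
                  list(sort(c("bcsA", "bcsB", "bcsZ", "bcsC")),
                       c("bcsB", "bcsZ")))
})

test_that("TU family deduplicates identical member sets and uses implicit TUs", {
  ann <- GenomeAnnotation(
    operons = list(o1 = c("a", "b"), o2 = c("c", "d")),
    tus = list(t1 = c("a", "b"), t2 = c("a", "b")),
    tuOperon = c(t1 = "o1", t2 = "o1"))
  tu <- buildTU(ann)
  expect_identical(length(tu), 2L)               # dedup + implicit whole o2
  expect_setequal(unname(geneSets(tu)), list(c("a", "b"), c("c", "d")))
  expect_true("t1" %in% names(tu))               # smallest id survives

  # operon with only the implicit TU: TU family equals OPR family
  annNoTU <- GenomeAnnotation(operons = list(o1 = c("a", "b", "c")))
  expect_identical(unname(geneSets(buildTU(annNoTU))),
                   unname(geneSets(buildOPR(annNoTU))))
})

test_that("COPR chunks the nested-promoter operon at TU boundaries", {
  copr <- buildCOPR(fig1Annotation())
  expect_identical(unname(geneSets(copr)),
                   list("bcsA", c("bcsB", "bcsZ"), "bcsC"))

  # suffix TU: cuts only at its start
  ann <- GenomeAnnotation(
    operons = list(o = c("g1", "g2", "g3")),
    tus = list(t1 = c("g1", "g2", "g3"), t2 = c("g2", "g3")),
    tuOperon = c(t1 = "o", t2 = "o"))
  expect_identical(unname(geneSets(buildCOPR(ann))),
                   list("g1", c("g2", "g3")))

  # no internal promoter: one chunk per operon
  annNoTU <- GenomeAnnotation(operons = list(o = c("a", "b", "c")))
  expect_identical(unname(geneSets(buildCOPR(annNoTU))),
                   list(c("a", "b", "c")))
})

test_that("COPR equals the exhaustive-segmentation oracle and partitions operon genes", {
  for (seed in 1:60) {
    ann <- randomSmallAnnotation(seed)
    got <- geneSets(buildCOPR(ann))
    expect_true(samePartition(got, bruteCOPR(ann)))
    members <- unlist(got, use.names = FALSE)
    expect_identical(anyDuplicated(members), 0L)
    expect_setequal(members, unlist(operons(ann), use.names = FALSE))
  }
})

test_that("TF sets split targets by merged role, at most four per TF", {
  tf <- buildTF(fig2Annotation())
  expect_setequal(sort(tf[["Fur.act"]]), c("sucA", "sucD"))
  expect_setequal(sort(tf[["Fur.rep"]]), c("cyoB", "entD", "sucB", "sucC"))

  allRoles <- GenomeAnnotation(
    operons = list(o = c("a", "b", "c", "d", "T")),
    interactions = data.frame(
      tf = "T", target = c("a", "b", "c", "d"),
      role = c("activation", "repression", "dual", "unknown")))
  fam <- buildTF(allRoles)
  expect_identical(length(fam), 4L)

  expect_identical(length(buildTF(GenomeAnnotation(
    operons = list(o = "a")))), 0L)

  for (seed in 1:40) {
    fam <- buildTF(randomSmallAnnotation(seed))
    tfOf <- sub("\\.(act|rep|dual|unk)$", "", names(fam))
    if (length(tfOf)) expect_lte(max(table(tfOf)), 4L)
  }
})

test_that("REG groups the Fur-regulon genes and SREG splits them by role", {
  ann <- fig2Annotation()
  reg <- geneSets(buildREG(ann))
  suc <- sort(c("sucA", "sucB", "sucC", "sucD"))
  expect_true(any(vapply(reg, function(s) identical(sort(s), suc), TRUE)))

  sreg <- geneSets(buildSREG(ann))
  sucSets <- Filter(function(s) any(s %in% suc), sreg)
  expect_length(sucSets, 2L)
  expect_setequal(lapply(unname(sucSets), sort),
                  list(c("sucA", "sucD"), c("sucB", "sucC")))
})

test_that("REG/SREG match the pairwise-comparison oracle; SREG refines REG", {
  for (seed in 1:60) {
    ann <- randomSmallAnnotation(seed)
    reg <- geneSets(buildREG(ann))
    sreg <- geneSets(buildSREG(ann))
    expect_true(samePartition(reg, bruteRegulons(ann, strict = FALSE)))
    expect_true(samePartition(sreg, bruteRegulons(ann, strict = TRUE)))
    # partitions of the regulated genes
    regulated <- unique(interactions(ann)$target)
    expect_setequal(as.character(unlist(reg, use.names = FALSE)), regulated)
    expect_identical(anyDuplicated(unlist(reg, use.names = FALSE)), 0L)
    # refinement: each strict regulon inside exactly one regulon
    for (s in sreg) {
      inside <- vapply(reg, function(r) all(s %in% r), TRUE)
      expect_identical(sum(inside), 1L)
    }
  }
})

test_that("builders emit maximal sets (no outside gene satisfies the predicate)", {
  for (seed in c(3, 14, 27)) {
    ann <- randomSmallAnnotation(seed)
    net <- interactions(ann)
    fam <- buildTF(ann)
    for (nm in names(fam)) {
      tfid <- sub("\\.(act|rep|dual|unk)$", "", nm)
      role <- c(act = "activation", rep = "repression", dual = "dual",
                unk = "unknown")[[sub("^.*\\.", "", nm)]]
      predicate <- net$target[net$tf == tfid & net$role == role]
      expect_setequal(fam[[nm]], predicate)
    }
    reg <- buildREG(ann)
    keys <- vapply(split(net$tf, net$target),
                   function(x) paste(sort(unique(x)), collapse = "+"), "")
    for (s in geneSets(reg))
      expect_setequal(s, names(keys)[keys == keys[[s[1]]]])
  }
})

test_that("randomization preserves set count, size multiset and overlap structure", {
  ann <- fig2Annotation()
  fam <- buildTF(ann)
  for (seed in c(1, 2, 99)) {
    rnd <- randomizeFamily(fam, seed = seed)
    expect_identical(setType(rnd), "RANDOMIZED")
    expect_identical(names(rnd), names(fam))
    expect_identical(setSizes(rnd), setSizes(fam))
    expect_setequal(geneUniverse(rnd), geneUniverse(fam))
    # overlap structure: all pairwise intersection sizes preserved
    for (i in seq_len(length(fam) - 1)) {
      for (j in seq(i + 1, length(fam))) {
        expect_identical(length(intersect(rnd[[i]], rnd[[j]])),
                         length(intersect(fam[[i]], fam[[j]])))
      }
    }
    expect_false(anyNA(unlist(geneSets(rnd))))
  }
})

test_that("identity permutation reproduces the family; explicit bijections are checked", {
  fam <- GeneSetFamily("EXTERNAL", list(s1 = c("a", "b"), s2 = c("c", "d", "e")))
  u <- geneUniverse(fam)
  idPerm <- setNames(u, u)
  rnd <- randomizeFamily(fam, permutation = idPerm)
  expect_identical(geneSets(rnd), geneSets(fam))
  expect_error(randomizeFamily(fam, permutation = c(a = "a")), "bijection")
  expect_error(randomizeFamily(GeneSetFamily("EXTERNAL")), "empty")
})

test_that("seeded randomization applies the same permutation sample() would draw", {
  fam <- GeneSetFamily("EXTERNAL",
                       list(s1 = c("g1", "g2"), s2 = c("g3", "g4", "g5")))
  u <- c("g1", "g2", "g3", "g4", "g5")
  perm <- withr::with_seed(7, setNames(sample(u), u))
  rnd <- randomizeFamily(fam, seed = 7)
  expect_identical(geneSets(rnd),
                   list(s1 = unname(perm[c("g1", "g2")]),
                        s2 = unname(perm[c("g3", "g4", "g5")])))
  expect_length(intersect(rnd[["s1"]], rnd[["s2"]]), 0L)
})

test_that("family statistics count sets, covered genes and set sizes", {
  fam <- GeneSetFamily("EXTERNAL", list(x = c("a", "b"), y = c("b", "c", "d")))
  st <- familyStats(fam)
  expect_identical(st$nSets, 2L)
  expect_identical(st$nGenes, 4L)
  expect_identical(st$meanSize, 2.5)
  expect_identical(st$maxSize, 3L)

  empty <- familyStats(GeneSetFamily("EXTERNAL"))
  expect_identical(empty$nSets, 0L)
  expect_true(is.na(empty$medianSize))

  copr <- familyStats(buildCOPR(fig1Annotation()))
  expect_identical(copr$nSets, 3L)
  expect_identical(copr$maxSize, 2L)
})

test_that("GMT files round-trip and malformed rows are handled", {
  fam <- buildTF(fig2Annotation())
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(fam, f)
  back <- readGMT(f)
  expect_identical(geneSets(back), geneSets(fam))

  dup <- withr::local_tempfile(lines = "s1\tdesc\tg1\tg1\tg2")
  expect_warning(fam2 <- readGMT(dup), "duplicate")
  expect_identical(fam2[["s1"]], c("g1", "g2"))

  short <- withr::local_tempfile(lines = "s1\tdesc")
  expect_error(readGMT(short), "3 fields")

  empty <- withr::local_tempfile(lines = character())
  expect_identical(length(readGMT(empty)), 0L)
})

test_that("GMT reader agrees with an independent parser", {
  skip_if_not_installed("fgsea")
  fam <- buildREG(fig2Annotation())
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(fam, f)
  ref <- fgsea::gmtPathways(f)
  got <- geneSets(readGMT(f))
  expect_identical(lapply(got, sort), lapply(ref, sort))
})
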