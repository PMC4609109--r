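test_that("set filtering intersects with the universe before thresholding", {
  genes <- sprintf("g%03d", 1:100)
  gsc <- methods::new("GeneSetCollection",
                      sets = list(s15 = genes[1:15], s16 = genes[1:16],
                                  s30 = c(genes[1:10],
                                          sprintf("x%02d", 1:20))),
                      setType = rep("category", 3), source = "test")
  f <- filterSets(gsc, genes)
  expect_setequal(names(geneSets(f)), "s16")     # 15 removed, 16 kept
  expect_length(geneSets(f)$s16, 16L)            # s30 has only 10 in-universe
  expect_length(geneSets(filterSets(gsc, genes, minSize = 10))$s30, 10L)
  expect_error(filterSets(gsc, character(0)), "universe")
})

test_that("binomial tail p-values match the exact choose() oracle", {
  genes <- sprintf("g%03d", 1:100)
  gsc <- methods::new("GeneSetCollection",
                      sets = list(K10 = genes[1:10]),
                      setType = "category", source = "test")
  sel <- c(genes[1:5], genes[50:54])       # overlap k = 5, n = 10
  res <- binomialEnrichment(sel, gsc, genes)
  expect_equal(res$p, exactBinomTail(5, 10, 0.1), tolerance = 1e-12)
  expect_equal(res$p, 1.634937e-3, tolerance = 1e-6)
  # empty overlap: p = 1
  res0 <- binomialEnrichment(genes[60:69], gsc, genes)
  expect_equal(res0$p, 1, tolerance = 1e-12)
  # saturated selection: k = K, p = P(X >= K) at success prob K/N
  resAll <- binomialEnrichment(genes, gsc, genes)
  expect_equal(resAll$n_hit, 10L)
  expect_equal(resAll$p, exactBinomTail(10, 100, 0.1), tolerance = 1e-12)
  expect_error(binomialEnrichment(c(genes[1], "zz"), gsc, genes),
               "outside the universe")
})

test_that("binomial p matches the oracle across random configurations", {
  set.seed(9)
  for (i in 1:50) {
    N <- sample(5:50, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    kMin <- max(0L, n - (N - K))       # realizable overlaps only
    kVals <- seq(kMin, min(n, K))
    k <- kVals[sample.int(length(kVals), 1)]
    genes <- sprintf("u%02d", 1:N)
    gsc <- methods::new("GeneSetCollection",
                        sets = list(s = genes[1:K]),
                        setType = "category", source = "test")
    nonset <- setdiff(genes, genes[seq_len(K)])
    sel <- c(genes[seq_len(k)],
             if (n > k) nonset[seq_len(n - k)])
    res <- binomialEnrichment(sel, gsc, genes)
    expect_equal(res$p, exactBinomTail(k, n, K / N), tolerance = 1e-12)
  }
})

test_that("Bonferroni keeps the familywise error under a null selection", {
  set.seed(10)
  genes <- sprintf("g%04d", 1:500)
  gsc <- generateGeneSets(genes, nSets = 20, sizeRange = c(16, 40),
                          seed = 12)
  hits <- vapply(1:200, function(i) {
    sel <- sample(genes, 30)
    any(binomialEnrichment(sel, gsc, genes, alpha = 0.05)$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("the running-sum ES matches brute-force enumeration", {
  # 5-gene toy with hand-checkable deltas
  scores <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  expect_equal(enrichmentScore(scores, c("g1", "g3")), 0.75)
  expect_equal(enrichmentScore(scores, c("g1", "g3")),
               bruteForceES(scores, c("g1", "g3")))
  expect_equal(enrichmentScore(scores, c("g4", "g5")),
               bruteForceES(scores, c("g4", "g5")))
  # randomized cases against the enumerator
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    sc <- setNames(rnorm(n), sprintf("r%03d", seq_len(n)))
    set <- sample(names(sc), sample(2:(n - 2), 1))
    for (expo in c(0, 1, 2))
      expect_equal(enrichmentScore(sc, set, expo),
                   bruteForceES(sc, set, expo), tolerance = 1e-12)
  }
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(12)
  sc <- setNames(rnorm(200), sprintf("f%03d", 1:200))
  set <- sample(names(sc), 25)
  ours <- enrichmentScore(sc, set, weightExponent = 1)
  sorted <- sort(sc, decreasing = TRUE)
  theirs <- fgsea::calcGseaStat(sorted,
                                which(names(sorted) %in% set),
                                gseaParam = 1)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("unweighted ES is invariant to monotone rescaling", {
  set.seed(13)
  sc <- setNames(rnorm(50), sprintf("m%02d", 1:50))
  set <- sample(names(sc), 10)
  a <- enrichmentScore(sc, set, weightExponent = 0)
  b <- enrichmentScore(setNames(exp(sc), names(sc)), set,
                       weightExponent = 0)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("a perfectly enriched set maximizes ES with a floor p-value", {
  set.seed(14)
  sc <- setNames(sort(rnorm(300), decreasing = TRUE),
                 sprintf("p%03d", 1:300))
  gsc <- methods::new("GeneSetCollection",
                      sets = list(top = names(sc)[1:20]),
                      setType = "category", source = "test")
  res <- rankedEnrichment(sc, gsc, nPerm = 500, seed = 1)
  expect_gt(res$ES, 0.9)
  expect_equal(res$direction, "up")
  expect_lte(res$p, 1 / 501)
  expect_warning(rankedEnrichment(sc, gsc, nPerm = 50, seed = 1),
                 "coarse")
})

test_that("ranked-enrichment p-values are calibrated for random sets", {
  set.seed(15)
  sc <- setNames(rnorm(400), sprintf("c%03d", 1:400))
  pvals <- vapply(1:100, function(i) {
    gsc <- methods::new("GeneSetCollection",
                        sets = list(s = sample(names(sc), 25)),
                        setType = "category", source = "null")
    rankedEnrichment(sc, gsc, nPerm = 200, seed = i)$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.0)
  expect_lte(mean(pvals < 0.05), 0.12)
})

test_that("both methods flag the planted set on synthetic data", {
  ds <- fixtureDataset()
  tae <- experiment(ds)
  universe <- geneIds(tae)
  filtered <- filterSets(ds@genesets, universe)
  top <- names(sort(abs(truthHsEffect(truth(ds))),
                    decreasing = TRUE))[1:100]
  bin <- binomialEnrichment(top, filtered, universe)
  expect_lt(bin$p[bin$set == "hs_biased"], 0.001)
  ps <- averageReplicates(globalNormalize(tae))
  dHS <- makeDelta(ps, "Anc_hs", "Anc_r")
  ge <- rankedEnrichment(dHS, filtered, nPerm = 500, seed = 2)
  expect_lte(ge$p[ge$set == "hs_regulon_true"], 1 / 501)
  expect_equal(ge$direction[ge$set == "hs_regulon_true"], "up")
})

test_that("GMT files round-trip sets and type tags", {
  gsc <- methods::new("GeneSetCollection",
                      sets = list(a = c("g1", "g2"), b = c("g3", "g4",
                                                           "g5")),
                      setType = c("category", "TF"), source = "test")
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(gsc, f)
  back <- readGmt(f)
  expect_identical(geneSets(back), geneSets(gsc))
  expect_identical(back@setType, gsc@setType)
  writeLines("oneset\tonly-two-fields", f)
  expect_error(readGmt(f), "fewer than 3 fields")
})
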