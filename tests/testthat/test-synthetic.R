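test_that("design arithmetic matches strains x (2 steady + hs) replicates", {
  expect_equal(nrow(generateDesign()), 32L)
  expect_equal(nrow(generateDesign(1, 1, "Anc")), 3L)
  expect_equal(nrow(generateDesign(2, 2, c("Anc", "41B"))), 12L)
  # property over a small grid
  for (ns in 1:3) for (nh in 1:2) for (k in 1:4) {
    strains <- c("Anc", "41B", "43B", "45L")[seq_len(k)]
    d <- generateDesign(ns, nh, strains)
    expect_equal(nrow(d), k * (2 * ns + nh))
    expect_false(anyDuplicated(
      paste(d$strain, d$condition, d$replicate)) > 0)
  }
})

test_that("design encodes temperatures and the optional ancestor e-arrays", {
  d <- generateDesign()
  expect_true(all(d$temperature_C[d$condition == "r"] == 36.9))
  expect_true(all(d$temperature_C[d$condition == "hs"] == 44.8))
  expect_equal(d$temperature_C[d$strain == "41B" & d$condition == "e"][1],
               41.2)
  expect_equal(nrow(generateDesign(includeAncE = FALSE)), 29L)
  expect_error(generateDesign(strains = c("Anc", "46X")), "46X")
})

test_that("truth draws hit the target genotype/temperature anti-correlation", {
  tr <- generateTruth(nGenes = 1000, seed = 1, gtAnticorr = -0.6)
  r <- cor(truthGenotypeEffect(tr)[, "45L"], truthTempEffect(tr)[, "45L"])
  expect_lt(abs(r - (-0.6)), 0.1)
})

test_that("truth respects degenerate and pass-through configurations", {
  tr0 <- generateTruth(nGenes = 100, seed = 3, genotypeSd = 0)
  expect_true(all(truthGenotypeEffect(tr0) == 0))
  tr <- generateTruth(nGenes = 1000, seed = 7, epistasisCoef = 0.25)
  expect_identical(tr@epistasisCoef, 0.25)
  expect_true(all(truthGenotypeEffect(tr)[, "Anc"] == 0))
  expect_error(generateTruth(100, gtAnticorr = 1.5), "gtAnticorr")
  expect_error(generateTruth(100, epistasisCoef = 1), "epistasisCoef")
  expect_error(generateTruth(100, noiseSd = NaN), "non-finite")
})

test_that("genotype effects accumulate along the serial lineage", {
  tr <- generateTruth(nGenes = 2000, seed = 2)
  G <- truthGenotypeEffect(tr)
  v <- apply(G, 2, var)
  expect_true(all(diff(v) > 0))  # Anc < 41B < 43B < 45L
  # each step adds an increment uncorrelated with the previous state
  inc <- G[, "43B"] - G[, "41B"]
  expect_lt(abs(cor(inc, G[, "41B"])), 0.1)
})

test_that("noise-free expression obeys the additive and damped models", {
  ds0 <- noiselessDataset(epistasisCoef = 0)
  ps <- averageReplicates(experiment(ds0))
  for (s in c("41B", "43B", "45L")) {
    ct <- epistasisContrasts(ps, s)
    expect_equal(deltaValues(ct$simultaneous), deltaValues(ct$additive),
                 tolerance = 1e-12)
  }
  ds <- simulateDataset(nGenes = 500, seed = 5, noiseSd = 0,
                        epistasisCoef = 0.25)
  ps <- averageReplicates(experiment(ds))
  ct <- epistasisContrasts(ps, "45L")
  fit <- epistasisRegression(ct$additive, ct$simultaneous)
  expect_equal(fit@slope, 0.75, tolerance = 1e-10)
  expect_equal(fit@magnitude, 0.25, tolerance = 1e-10)
})

test_that("an all-zero truth yields baseline-only uncorrelated profiles", {
  tr <- generateTruth(nGenes = 400, seed = 9, baselineSd = 1.5,
                      regulonFraction = 0, hsGlobalSd = 0,
                      genotypeSd = 0, tempSd = 0, noiseSd = 0.3)
  tae <- generateExpression(tr, generateDesign())
  centered <- exprsValues(tae) - truthBaseline(tr)
  cm <- cor(centered)
  offdiag <- cm[upper.tri(cm)]
  expect_lt(max(abs(offdiag)), 0.2)
})

test_that("the generator is deterministic for a fixed seed", {
  a <- simulateDataset(nGenes = 200, seed = 42)
  b <- simulateDataset(nGenes = 200, seed = 42)
  expect_identical(exprsValues(experiment(a)), exprsValues(experiment(b)))
  expect_identical(geneSets(a), geneSets(b))
  expect_identical(truthHsEffect(truth(a)), truthHsEffect(truth(b)))
  c <- simulateDataset(nGenes = 200, seed = 43)
  expect_false(identical(exprsValues(experiment(a)),
                         exprsValues(experiment(c))))
})

test_that("gene-set generation respects sizes and plants enrichment", {
  genes <- sprintf("g%04d", 1:1000)
  gs <- generateGeneSets(genes, nSets = 20, sizeRange = c(16, 50),
                         seed = 3)
  sz <- lengths(geneSets(gs))
  expect_length(sz, 20L)
  expect_true(all(sz >= 16 & sz <= 50))
  one <- generateGeneSets(genes[1:50], nSets = 1, sizeRange = c(16, 16),
                          seed = 1)
  expect_equal(lengths(geneSets(one)), c(GS01 = 16L))
  expect_error(generateGeneSets(genes[1:10], 1, c(16, 16)), "infeasible")

  scores <- setNames(c(seq(5, 0.6, length.out = 100), rep(0.1, 900)),
                     genes)
  gsP <- generateGeneSets(genes, nSets = 0, seed = 4,
                          planted = list(name = "planted",
                                         scores = scores, topN = 100,
                                         odds = 10, size = 40))
  top <- names(sort(abs(scores), decreasing = TRUE))[1:100]
  res <- binomialEnrichment(top, gsP, genes)
  expect_lt(res$p[res$set == "planted"], 0.001)
})

test_that("dataset files round-trip through the writers", {
  ds <- fixtureDataset(nGenes = 120, seed = 8,
                       genesetArgs = list(nSets = 3,
                                          sizeRange = c(16, 20)))
  dir <- withr::local_tempdir()
  paths <- writeDataset(ds, dir)
  expect_true(all(file.exists(paths)))
  m <- readExpressionMatrix(paths[["matrix"]])
  expect_equal(m, exprsValues(experiment(ds)), tolerance = 1e-12)
  gs <- readGmt(paths[["genesets"]])
  expect_identical(geneSets(gs), geneSets(ds))
  sidecar <- jsonlite::read_json(paths[["truth"]])
  expect_equal(sidecar$epistasisCoef, truth(ds)@epistasisCoef)
})
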