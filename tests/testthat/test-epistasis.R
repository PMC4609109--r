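test_that("the ancestor self-comparison is exactly additive", {
  ds <- noiselessDataset()
  ps <- averageReplicates(experiment(ds))
  ct <- epistasisContrasts(ps, "Anc")
  expect_true(all(deltaValues(ct$dG) == 0))
  expect_equal(deltaValues(ct$simultaneous), deltaValues(ct$dHS_A),
               tolerance = 1e-12)
  fit <- epistasisRegression(ct$additive, ct$simultaneous,
                             strain = "Anc")
  expect_equal(fit@slope, 1, tolerance = 1e-10)
  expect_equal(fit@magnitude, 0, tolerance = 1e-10)
  expect_error(epistasisContrasts(ps, "46X"), "missing profile")
})

test_that("noise-free damped data give slope 1 - e for every strain", {
  ds <- simulateDataset(nGenes = 400, seed = 21, noiseSd = 0,
                        epistasisCoef = 0.3)
  ps <- averageReplicates(experiment(ds))
  for (s in c("41B", "43B", "45L")) {
    ct <- epistasisContrasts(ps, s)
    fit <- epistasisRegression(ct$additive, ct$simultaneous, strain = s)
    expect_equal(fit@slope, 0.7, tolerance = 1e-10)
  }
})

test_that("delta association reports Pearson r with t-based p", {
  v <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  mk <- function(x, lab) methods::new("DeltaProfile", values = x,
                                      label = lab, minuend = "a",
                                      subtrahend = "b")
  expect_equal(deltaAssociation(mk(v, "x"), mk(v, "y"))$r, 1,
               tolerance = 1e-12)
  expect_equal(deltaAssociation(mk(v, "x"), mk(-v, "y"))$r, -1,
               tolerance = 1e-12)
  expect_error(deltaAssociation(mk(v, "x"), mk(v * 0, "y")),
               "zero-variance")
  # p matches the closed-form t transform
  set.seed(22)
  w <- setNames(rnorm(50), names(v))
  out <- deltaAssociation(mk(v, "x"), mk(w, "y"))
  tt <- out$r * sqrt(48 / (1 - out$r^2))
  expect_equal(out$p, 2 * pt(-abs(tt), 48), tolerance = 1e-12)
})

test_that("independently drawn genotype and heat-shock effects decorrelate", {
  ds <- fixtureDataset(nGenes = 2000, seed = 31)
  ps <- averageReplicates(globalNormalize(experiment(ds)))
  ct <- epistasisContrasts(ps, "45L")
  expect_lt(abs(deltaAssociation(ct$dHS_A, ct$dG)$r), 0.1)
})

test_that("exact linear data recover the slope in closed form", {
  x <- setNames(seq(-3, 3, length.out = 60), sprintf("g%02d", 1:60))
  mk <- function(v, lab) methods::new("DeltaProfile", values = v,
                                      label = lab, minuend = "a",
                                      subtrahend = "b")
  fit <- epistasisRegression(mk(x, "add"), mk(0.75 * x, "sim"))
  expect_equal(fit@slope, 0.75, tolerance = 1e-12)
  expect_equal(fit@magnitude, 0.25, tolerance = 1e-12)
  ident <- epistasisRegression(mk(x, "add"), mk(x, "sim"))
  expect_equal(ident@magnitude, 0, tolerance = 1e-12)
  expect_error(epistasisRegression(mk(x * 0 + 1, "add"), mk(x, "sim")),
               "zero variance")
  expect_error(epistasisRegression(mk(x, "add"), mk(x, "sim"),
                                   genes = c("g01", "g02")),
               "at least 3 genes")
})

test_that("estimated magnitude is scale-equivariant", {
  ds <- fixtureDataset(nGenes = 1000, seed = 41, epistasisCoef = 0.25)
  ps <- averageReplicates(experiment(ds))
  ct <- epistasisContrasts(ps, "45L")
  f1 <- epistasisRegression(ct$additive, ct$simultaneous)
  scaled <- toyProfiles(profileValues(ps) * 3.7)
  ct2 <- epistasisContrasts(scaled, "45L")
  f2 <- epistasisRegression(ct2$additive, ct2$simultaneous)
  expect_equal(f2@slope, f1@slope, tolerance = 1e-10)
})

test_that("magnitude recovery is approximately unbiased under noise", {
  # small-scale version of the full recovery study (acceptance suite)
  est <- vapply(1:5, function(seed) {
    ds <- simulateDataset(nGenes = 1000, seed = 200 + seed,
                          noiseSd = 0.3, epistasisCoef = 0.25)
    ps <- averageReplicates(experiment(ds))
    ct <- epistasisContrasts(ps, "45L")
    epistasisRegression(ct$additive, ct$simultaneous)@magnitude
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.25), 0.05)
})

test_that("restricting to the most-changed genes sharpens the slope", {
  ds <- fixtureDataset(nGenes = 2000, seed = 31)
  ps <- averageReplicates(experiment(ds))
  ct <- epistasisContrasts(ps, "45L")
  x <- deltaValues(ct$additive)
  y <- deltaValues(ct$simultaneous)
  se <- function(genes) {
    fit <- lm(y[genes] ~ x[genes])
    summary(fit)$coefficients[2, 2]
  }
  top <- names(sort(abs(x), decreasing = TRUE))[1:400]
  set.seed(51)
  rand <- sample(names(x), 400)
  expect_lt(se(top), se(rand))
})

test_that("epistasisTable covers every evolved strain with dHS~dG stats", {
  ps <- fixtureProfiles()
  tab <- epistasisTable(ps)
  expect_setequal(names(tab), c("41B", "43B", "45L"))
  df <- epistasisAsDataFrame(tab)
  expect_equal(nrow(df), 3L)
  expect_true(all(df$magnitude == 1 - df$slope))
  expect_true(all(df$n_genes == length(geneIds(ps))))
})

test_that("responsiveness alignment rises along the lineage and with beta", {
  ps <- fixtureProfiles()
  r <- vapply(c("41B", "43B", "45L"), responsivenessAlignment,
              numeric(1), profiles = ps)
  expect_true(all(diff(r) > 0))
  # direct construction: dT equal to dHS_A gives r = 1
  v <- profileValues(ps)
  v2 <- v
  v2[, "45L_e"] <- v2[, "45L_r"] + (v[, "Anc_hs"] - v[, "Anc_r"])
  expect_equal(responsivenessAlignment(toyProfiles(v2), "45L"), 1,
               tolerance = 1e-12)
  # monotone in the generator's heat-shock alignment coefficient
  rGrid <- vapply(c(0.05, 0.3, 0.6), function(beta) {
    align <- c(Anc = 0.2, "41B" = 0.05, "43B" = 0.1, "45L" = beta)
    ds <- simulateDataset(nGenes = 800, seed = 61, hsAlign = align)
    responsivenessAlignment(
      averageReplicates(experiment(ds)), "45L")
  }, numeric(1))
  expect_true(all(diff(rGrid) > 0))
})

test_that("independent synthetic effects leave dHS_A and dT uncorrelated", {
  align <- c(Anc = 0, "41B" = 0, "43B" = 0, "45L" = 0)
  ds <- simulateDataset(nGenes = 2000, seed = 71, hsAlign = align,
                        gtAnticorr = 0)
  ps <- averageReplicates(experiment(ds))
  expect_lt(abs(responsivenessAlignment(ps, "45L")), 0.1)
})
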