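# Synthetic-data generator with known ground truth.
#
# The generator emulates the structure of a thermal-adaptation array
# study: a serial lineage of strains accumulating mutation effects, a
# dominant shared heat-shock response, evolution-temperature steady-state
# effects anti-correlated with the genotype effects, and a multiplicative
# epistatic cancellation of the combined genotype + heat-shock effect.

.DEFAULT_STRAINS <- c("Anc", "41B", "43B", "45L")
.DEFAULT_EVO_TEMPS <- c(Anc = 44.8, "41B" = 41.2, "43B" = 43.2, "45L" = 44.8)

# Baseline growth-rate table (1/h) used to attach a fitness variable to
# each simulated array: evolved strains grow slightly faster than the
# ancestor at the regular temperature (improved fitness), recover growth
# at their evolution temperature, while the un-adapted ancestor grows
# poorly at the reference high temperature; heat-shocked cultures are
# transiently growth-arrested.
.growthRateBase <- function(strain, condition, strains) {
  i <- match(strain, strains) - 1L          # 0 for ancestor
  switch(condition,
         r  = 0.70 + 0.03 * i,
         e  = if (i == 0L) 0.20 else 0.68 - 0.04 * i,
         hs = 0.25)
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate the sample design of a thermal-adaptation study
#'
#' One row per array: each strain contributes `nSteadyReps` arrays of
#' exponential growth at the regular temperature (condition `r`),
#' `nSteadyReps` at its evolution temperature (condition `e`) and
#' `nHsReps` heat-shock arrays (condition `hs`). The default reproduces
#' the 4-strain, 32-array design (triplicate r, triplicate e, duplicate
#' hs). Whether the ancestor is assayed at the reference high temperature
#' (its `e` arrays, at 44.8 degrees C) is configurable via `includeAncE`.
#'
#' @param nSteadyReps replicates per steady condition (>= 1).
#' @param nHsReps replicates per heat-shock condition (>= 1).
#' @param strains strain labels; the first is treated as the ancestor.
#' @param evolutionTemps named vector of evolution temperatures (degrees
#'   C) for each strain; must cover `strains`.
#' @param regularTemp,hsTemp regular-growth and heat-shock temperatures.
#' @param includeAncE include steady `e` arrays for the ancestor.
#' @return data.frame with columns `sample_id`, `strain`, `condition`,
#'   `replicate`, `temperature_C`.
#' @examples
#' nrow(generateDesign())  # 32 arrays
#' @export
generateDesign <- function(nSteadyReps = 3L, nHsReps = 2L,
                           strains = .DEFAULT_STRAINS,
                           evolutionTemps = .DEFAULT_EVO_TEMPS,
                           regularTemp = 36.9, hsTemp = 44.8,
                           includeAncE = TRUE) {
  stopifnot(nSteadyReps >= 1L, nHsReps >= 1L, length(strains) >= 1L)
  unknown <- setdiff(strains, names(evolutionTemps))
  if (length(unknown))
    stop("no evolution temperature for strain(s): ",
         paste(unknown, collapse = ", "))
  rows <- list()
  for (s in strains) {
    conds <- c(rep("r", nSteadyReps),
               if (s != strains[1L] || includeAncE) rep("e", nSteadyReps),
               rep("hs", nHsReps))
    for (cc in unique(conds)) {
      reps <- sum(conds == cc)
      temp <- switch(cc, r = regularTemp, e = evolutionTemps[[s]],
                     hs = hsTemp)
      rows[[paste(s, cc)]] <- data.frame(
        sample_id = paste(s, cc, seq_len(reps), sep = "_"),
        strain = s, condition = cc, replicate = seq_len(reps),
        temperature_C = temp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw ground-truth effect vectors for a synthetic dataset
#'
#' Per-gene effects are drawn as follows (all in log2 units):
#' * baseline ~ Normal(0, `baselineSd`);
#' * heat-shock effect: a planted regulon (fraction `regulonFraction` of
#'   genes) with effects ~ Normal(`regulonMean`, `regulonSd`), and a
#'   broad global component ~ Normal(0, `hsGlobalSd`) for the remaining
#'   genes (a transcriptome-wide growth-arrest shift, which is what makes
#'   the heat-shock axis dominate condition clustering);
#' * genotype effects accumulate along the serial lineage: each
#'   evolutionary step adds an independent sparse increment (a fraction
#'   `genotypeFraction` of genes affected, effects ~ Normal(0,
#'   `genotypeSd`)); the ancestor's effect is identically zero;
#' * temperature effects per strain are a correlated mixture targeting
#'   correlation `gtAnticorr` with that strain's genotype effect, plus a
#'   small strain-specific alignment `hsAlign` with the heat-shock
#'   response.
#'
#' @param nGenes number of genes (>= 2).
#' @param seed integer RNG seed; the draw is deterministic given the seed.
#' @param strains strain labels, ancestor first.
#' @param baselineSd baseline log-expression SD.
#' @param regulonFraction,regulonMean,regulonSd planted heat-shock
#'   regulon: fraction of genes, effect mean and SD.
#' @param hsGlobalSd SD of the global heat-shock component outside the
#'   regulon.
#' @param genotypeFraction,genotypeSd per-step sparse genotype increment:
#'   fraction of genes affected and the effect SD for affected genes.
#' @param tempSd SD of the evolution-temperature steady-state effect.
#' @param gtAnticorr target correlation between genotype and temperature
#'   effects (negative for the inverse relationship), |rho| < 1.
#' @param hsAlign named per-strain alignment of the temperature effect
#'   with the heat-shock response (un-adapted ancestor highest).
#' @param epistasisCoef fraction of the combined genotype + heat-shock
#'   effect cancelled in evolved strains, in [0, 1).
#' @param noiseSd replicate noise SD.
#' @return a [SyntheticTruth-class].
#' @export
generateTruth <- function(nGenes = 4383L, seed = 1L,
                          strains = .DEFAULT_STRAINS,
                          baselineSd = 1.5,
                          regulonFraction = 0.05, regulonMean = 2,
                          regulonSd = 0.7, hsGlobalSd = 1.7,
                          genotypeFraction = 0.2, genotypeSd = sqrt(3),
                          tempSd = 0.8, gtAnticorr = -0.5,
                          hsAlign = NULL, epistasisCoef = 0.25,
                          noiseSd = 0.3) {
  stopifnot(nGenes >= 2L, length(strains) >= 1L)
  cfg <- list(baselineSd = baselineSd, regulonFraction = regulonFraction,
              regulonMean = regulonMean, regulonSd = regulonSd,
              hsGlobalSd = hsGlobalSd, genotypeFraction = genotypeFraction,
              genotypeSd = genotypeSd, tempSd = tempSd,
              gtAnticorr = gtAnticorr, epistasisCoef = epistasisCoef,
              noiseSd = noiseSd)
  bad <- names(cfg)[!vapply(cfg, function(v) all(is.finite(v)), logical(1))]
  if (length(bad))
    stop("non-finite configuration value(s): ", paste(bad, collapse = ", "))
  if (abs(gtAnticorr) >= 1) stop("|gtAnticorr| must be < 1")
  if (epistasisCoef < 0 || epistasisCoef >= 1)
    stop("epistasisCoef must lie in [0, 1)")
  if (regulonFraction < 0 || regulonFraction > 1)
    stop("regulonFraction must lie in [0, 1]")
  if (is.null(hsAlign)) {
    k <- length(strains)
    hsAlign <- if (k == 1L) c(0.2) else c(0.2, 0.05 * seq_len(k - 1L))
    names(hsAlign) <- strains
  }
  if (is.null(names(hsAlign)) || !all(strains %in% names(hsAlign)))
    stop("hsAlign must be named and cover all strains")

  genes <- sprintf("g%04d", seq_len(nGenes))
  .withSeed(seed, {
    baseline <- setNames(rnorm(nGenes, 0, baselineSd), genes)
    nReg <- round(regulonFraction * nGenes)
    regulon <- sample(genes, nReg)
    hs <- setNames(rnorm(nGenes, 0, hsGlobalSd), genes)
    hs[regulon] <- rnorm(nReg, regulonMean, regulonSd)
    G <- matrix(0, nGenes, length(strains),
                dimnames = list(genes, strains))
    if (length(strains) > 1L) {
      for (j in 2:length(strains)) {
        inc <- rbinom(nGenes, 1L, genotypeFraction) *
          rnorm(nGenes, 0, genotypeSd)
        G[, j] <- G[, j - 1L] + inc
      }
    }
    Tm <- matrix(0, nGenes, length(strains),
                 dimnames = list(genes, strains))
    for (j in seq_along(strains)) {
      z <- rnorm(nGenes)
      g <- G[, j]
      gstd <- if (sd(g) > 0) (g - mean(g)) / sd(g) else numeric(nGenes)
      Tm[, j] <- gtAnticorr * tempSd * gstd +
        sqrt(1 - gtAnticorr^2) * tempSd * z +
        hsAlign[[strains[j]]] * hs
    }
    methods::new("SyntheticTruth", baseline = baseline, hsEffect = hs,
                 genotypeEffect = G, tempEffect = Tm,
                 hsRegulon = sort(regulon),
                 epistasisCoef = epistasisCoef, gtAnticorr = gtAnticorr,
                 noiseSd = noiseSd, seed = as.integer(seed),
                 params = c(cfg, list(hsAlign = hsAlign,
                                      strains = strains)))
  })
}

#' Simulate log expression for a design under a ground truth
#'
#' The log expression of gene g on an array of strain s is
#' * condition r: `baseline + G[g,s] + noise`;
#' * condition e: `baseline + G[g,s] + T[g,s] + noise`;
#' * condition hs: `baseline + (1 - e) * (G[g,s] + hsEffect) + noise` for
#'   evolved strains, and `baseline + hsEffect + noise` for the ancestor
#'   (whose genotype effect is zero and whose heat-shock response is
#'   undamped),
#'
#' where `e` is the epistasis coefficient. By construction the
#' population regression slope of the simultaneous change
#' (strain_hs - Anc_r) on the additive change (dG + dHS_A) equals
#' `1 - e`. Noise is i.i.d. Normal(0, `noiseSd`) per gene and array,
#' drawn from a stream seeded by `truth@seed + 1`. Synthetic per-array
#' growth rates are attached (fast steady growth, recovered growth at
#' evolution temperatures, transient arrest under heat shock).
#'
#' @param truth a [SyntheticTruth-class].
#' @param design data.frame from [generateDesign()]; all strains must be
#'   covered by the truth.
#' @return a [ThermalArrayExperiment-class].
#' @export
generateExpression <- function(truth, design) {
  stopifnot(methods::is(truth, "SyntheticTruth"), nrow(design) >= 1L)
  strains <- colnames(truth@genotypeEffect)
  unknown <- setdiff(unique(design$strain), strains)
  if (length(unknown))
    stop("truth does not cover strain(s): ",
         paste(unknown, collapse = ", "))
  genes <- geneIds(truth)
  n <- length(genes)
  e <- truth@epistasisCoef
  anc <- strains[1L]
  .withSeed(truth@seed + 1L, {
    cols <- matrix(NA_real_, n, nrow(design),
                   dimnames = list(genes, design$sample_id))
    for (i in seq_len(nrow(design))) {
      s <- design$strain[i]
      mu <- switch(design$condition[i],
        r  = truth@baseline + truth@genotypeEffect[, s],
        e  = truth@baseline + truth@genotypeEffect[, s] +
             truth@tempEffect[, s],
        hs = if (s == anc) truth@baseline + truth@hsEffect
             else truth@baseline +
               (1 - e) * (truth@genotypeEffect[, s] + truth@hsEffect))
      cols[, i] <- mu + rnorm(n, 0, truth@noiseSd)
    }
    meta <- design
    meta$growth_rate <- vapply(seq_len(nrow(design)), function(i)
      .growthRateBase(design$strain[i], design$condition[i], strains) +
        rnorm(1L, 0, 0.02), numeric(1))
    ThermalArrayExperiment(cols, meta)
  })
}

#' Generate a gene-set collection, optionally with a planted enrichment
#'
#' Draws `nSets` named sets by sampling genes without replacement, with
#' sizes uniform in `sizeRange`. A planted set is drawn preferentially
#' from the top of a supplied truth-derived score: genes in the top
#' `planted$topN` by absolute score receive `planted$odds` times the
#' sampling weight of the remaining genes.
#'
#' @param genes universe of gene ids.
#' @param nSets number of random sets.
#' @param sizeRange integer `c(min, max)` set size; `max` must not exceed
#'   the number of genes.
#' @param planted optional list with elements `name`, `scores` (named
#'   numeric, e.g. `abs(hsEffect)`), `topN` (default 100), `odds`
#'   (default 10) and `size` (default mean of `sizeRange`).
#' @param seed integer RNG seed.
#' @param setType annotation tag for the sets (e.g. `"category"`).
#' @param source free-text provenance.
#' @return a [GeneSetCollection-class].
#' @export
generateGeneSets <- function(genes, nSets = 20L, sizeRange = c(16L, 50L),
                             planted = NULL, seed = 1L,
                             setType = "category",
                             source = "synthetic") {
  stopifnot(length(genes) >= 1L, nSets >= 0L)
  sizeRange <- as.integer(sizeRange)
  if (length(sizeRange) != 2L || sizeRange[1L] > sizeRange[2L] ||
      sizeRange[1L] < 1L || sizeRange[2L] > length(genes))
    stop("infeasible sizeRange for ", length(genes), " genes")
  .withSeed(seed, {
    sets <- list()
    if (nSets > 0L) {
      sizes <- if (sizeRange[1L] == sizeRange[2L]) rep(sizeRange[1L], nSets)
               else sample(seq(sizeRange[1L], sizeRange[2L]), nSets,
                           replace = TRUE)
      for (i in seq_len(nSets))
        sets[[sprintf("GS%02d", i)]] <- sort(sample(genes, sizes[i]))
    }
    if (!is.null(planted)) {
      topN <- planted$topN %||% 100L
      odds <- planted$odds %||% 10
      size <- planted$size %||% round(mean(sizeRange))
      scores <- planted$scores
      if (is.null(names(scores)) || !all(names(scores) %in% genes))
        stop("planted$scores must be named by in-universe genes")
      top <- names(sort(abs(scores), decreasing = TRUE))[seq_len(topN)]
      w <- ifelse(genes %in% top, odds, 1)
      sets[[planted$name %||% "planted"]] <-
        sort(sample(genes, size, prob = w))
    }
    methods::new("GeneSetCollection", sets = sets,
                 setType = rep(setType, length(sets)), source = source)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic dataset
#'
#' Composes [generateDesign()], [generateTruth()], [generateExpression()]
#' and [generateGeneSets()] into a [SyntheticDataset-class]. The default
#' gene-set collection contains random sets plus two informative ones:
#' the true planted heat-shock regulon (`"hs_regulon_true"`) and a set
#' drawn with 10:1 odds from the top-100 genes by absolute heat-shock
#' effect (`"hs_biased"`).
#'
#' @param nGenes number of genes.
#' @param seed integer RNG seed for the whole dataset.
#' @param design optional design data.frame; defaults to
#'   [generateDesign()] under `designArgs`.
#' @param designArgs list of arguments to [generateDesign()].
#' @param genesetArgs list of arguments to [generateGeneSets()]
#'   (`nSets`, `sizeRange`).
#' @param ... passed to [generateTruth()].
#' @return a [SyntheticDataset-class].
#' @examples
#' d <- simulateDataset(nGenes = 200, seed = 1)
#' d
#' @export
simulateDataset <- function(nGenes = 4383L, seed = 1L, design = NULL,
                            designArgs = list(), genesetArgs = list(),
                            ...) {
  tr <- generateTruth(nGenes = nGenes, seed = seed, ...)
  if (is.null(design)) design <- do.call(generateDesign, designArgs)
  tae <- generateExpression(tr, design)
  genes <- geneIds(tr)
  topN <- min(nGenes, max(100L, round(0.1 * nGenes)))
  gs <- do.call(generateGeneSets, c(list(
    genes = genes,
    planted = list(name = "hs_biased", scores = abs(truthHsEffect(tr)),
                   topN = topN, odds = 10),
    seed = seed + 2L), genesetArgs))
  gs@sets[["hs_regulon_true"]] <- tr@hsRegulon
  gs@setType <- c(gs@setType, "category")
  methods::new("SyntheticDataset", experiment = tae, genesets = gs,
               truth = tr)
}

#' Ground-truth component accessors
#'
#' @param x a [SyntheticTruth-class].
#' @return the named per-gene effect vector (or genes x strains matrix
#'   for genotype/temperature effects).
#' @export
truthHsEffect <- function(x) x@hsEffect

#' @rdname truthHsEffect
#' @export
truthGenotypeEffect <- function(x) x@genotypeEffect

#' @rdname truthHsEffect
#' @export
truthTempEffect <- function(x) x@tempEffect

#' @rdname truthHsEffect
#' @export
truthBaseline <- function(x) x@baseline

#' @rdname truthHsEffect
#' @export
truthHsRegulon <- function(x) x@hsRegulon

#' Write a synthetic dataset to disk
#'
#' Writes the expression matrix TSV, sample-sheet TSV, gene sets in GMT
#' format and the ground-truth parameters as a JSON sidecar.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @param header optional comment line(s) prefixed to the TSV files.
#' @return named character vector of the four file paths, invisibly.
#' @export
writeDataset <- function(dataset, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- dataset@truth
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             samples = file.path(dir, "samples.tsv"),
             genesets = file.path(dir, "genesets.gmt"),
             truth = file.path(dir, "truth.json"))
  writeExpressionMatrix(dataset@experiment, paths[["matrix"]],
                        header = header)
  writeSampleSheet(sampleMeta(dataset@experiment), paths[["samples"]],
                   header = header)
  writeGmt(dataset@genesets, paths[["genesets"]])
  sidecar <- list(seed = tr@seed, epistasisCoef = tr@epistasisCoef,
                  gtAnticorr = tr@gtAnticorr, noiseSd = tr@noiseSd,
                  nGenes = length(tr@baseline),
                  strains = colnames(tr@genotypeEffect),
                  hsRegulon = tr@hsRegulon,
                  params = tr@params[setdiff(names(tr@params),
                                             c("strains"))])
  jsonlite::write_json(sidecar, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
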