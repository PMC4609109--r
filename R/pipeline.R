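# End-to-end orchestration: configuration, simulation to disk, and the
# full analysis pipeline with per-stage TSV outputs and logging.

.pkgVersion <- function()
  as.character(utils::packageVersion("ThermAdapt"))

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[order(names(config))]),
                   collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

.stamp <- function(config, seed)
  sprintf("ThermAdapt %s | config=%s | seed=%d", .pkgVersion(),
          .configHash(config), as.integer(seed))

.log <- function(logFile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(logFile)) cat(msg, "\n", file = logFile, append = TRUE)
}

#' Read a pipeline run configuration
#'
#' YAML with either an `input` block (`matrix`, `samples`, `genesets`
#' paths) or a `simulate` block (arguments to [simulateDataset()]), but
#' not both, plus optional `analysis` parameters (`linkage`,
#' `tail_fraction`, `n_perm`, `alpha`, `min_set_size`,
#' `skip_enrichment`), `out` and `seed`.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  hasIn <- !is.null(cfg$input)
  hasSim <- !is.null(cfg$simulate)
  if (hasIn == hasSim)
    stop("config must have exactly one of 'input' or 'simulate'")
  cfg
}

#' Simulate a dataset and write it to disk
#'
#' Writes `matrix.tsv`, `samples.tsv`, `genesets.gmt` and `truth.json`
#' into `outDir`; every text output carries a header with the package
#' version, a configuration hash and the seed.
#'
#' @param outDir output directory.
#' @param seed integer RNG seed.
#' @param nGenes number of genes.
#' @param ... further arguments to [simulateDataset()].
#' @param logFile optional log file path.
#' @return the [SyntheticDataset-class], invisibly.
#' @export
simulateRun <- function(outDir, seed = 1L, nGenes = 4383L, ...,
                        logFile = NULL) {
  cfg <- c(list(nGenes = nGenes, seed = seed), list(...))
  stamp <- .stamp(cfg, seed)
  .log(logFile, "simulate: nGenes=", nGenes, " seed=", seed)
  ds <- simulateDataset(nGenes = nGenes, seed = seed, ...)
  writeDataset(ds, outDir, header = stamp)
  .log(logFile, "simulate: wrote ", outDir, " (",
       ncol(experiment(ds)), " arrays)")
  invisible(ds)
}

#' Run the full analysis pipeline
#'
#' Normalize, average replicates, cluster conditions, compute the
#' correlation matrix, PCA with top-loaded gene selection (and growth
#' correlation when rates are available), both enrichment methods, and
#' the per-strain epistasis decomposition. One TSV per stage plus a
#' machine-readable `summary.json` are written to `outDir`; a stage
#' failure aborts with the stage name and leaves a `FAILED` marker.
#'
#' @param x a [ThermalArrayExperiment-class], or path to an expression
#'   matrix TSV (then `samples` must be the sample-sheet path).
#' @param samples sample-sheet path when `x` is a file path.
#' @param genesets a [GeneSetCollection-class] or GMT path; NULL skips
#'   enrichment.
#' @param outDir output directory.
#' @param seed RNG seed (permutations).
#' @param linkage,distance clustering configuration.
#' @param tailFraction per-tail fraction for PC gene selection.
#' @param nPerm ranked-enrichment permutations.
#' @param alpha binomial significance threshold (Bonferroni-adjusted).
#' @param minSetSize smallest retained in-universe set size.
#' @param skipEnrichment skip both enrichment stages.
#' @param normalize apply global median normalization first.
#' @param logFile optional log file (default `run.log` in `outDir`).
#' @return invisible list with all stage results.
#' @export
analyzePipeline <- function(x, samples = NULL, genesets = NULL,
                            outDir, seed = 1L,
                            distance = "pearson", linkage = "average",
                            tailFraction = 0.05, nPerm = 1000L,
                            alpha = 0.001, minSetSize = 16L,
                            skipEnrichment = FALSE, normalize = TRUE,
                            logFile = file.path(outDir, "run.log")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(seed = seed, distance = distance, linkage = linkage,
              tailFraction = tailFraction, nPerm = nPerm, alpha = alpha,
              minSetSize = minSetSize, skipEnrichment = skipEnrichment,
              normalize = normalize)
  stamp <- .stamp(cfg, seed)
  marker <- file.path(outDir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  stage <- function(name, expr) {
    .log(logFile, "stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 marker)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  res <- list(config = cfg)
  tae <- stage("load", {
    if (methods::is(x, "ThermalArrayExperiment")) x
    else {
      if (is.null(samples))
        stop("a sample sheet is required with a matrix path")
      ThermalArrayExperiment(readExpressionMatrix(x),
                             readSampleSheet(samples))
    }
  })
  if (is.character(genesets)) genesets <- readGmt(genesets)
  .log(logFile, "loaded ", nrow(tae), " genes x ", ncol(tae), " arrays")

  if (normalize) tae <- stage("normalize", globalNormalize(tae))
  res$experiment <- tae
  profiles <- stage("average", averageReplicates(tae))
  res$profiles <- profiles
  writeExpressionMatrix(profiles, file.path(outDir, "profiles.tsv"),
                        header = stamp)

  res$dendrogram <- stage("cluster",
                          clusterProfiles(profiles, distance, linkage))
  dendrogramNewick(res$dendrogram, file.path(outDir, "dendrogram.nwk"))
  res$correlations <- stage("correlation", correlationMatrix(profiles))
  writeComparativeTsv(res$correlations,
                      file.path(outDir, "correlations.tsv"),
                      header = stamp)

  res$pca <- stage("pca", runPCA(tae))
  writePcaTsv(res$pca, file.path(outDir, "pca"), header = stamp)
  nTop <- min(4L, length(varianceFraction(res$pca)))
  res$topGenes <- stage("top-genes", {
    tg <- lapply(paste0("PC", seq_len(nTop)), function(pc)
      topLoadedGenes(res$pca, pc, tailFraction))
    names(tg) <- paste0("PC", seq_len(nTop))
    for (pc in names(tg))
      writeLines(tg[[pc]], file.path(outDir, paste0("top_", pc, ".txt")))
    tg
  })
  gr <- SummarizedExperiment::colData(tae)$growth_rate
  if (!is.null(gr) && !anyNA(gr))
    res$growthCorrelation <- stage("growth-correlation",
                                   pcGrowthCorrelation(res$pca, tae))

  if (!skipEnrichment && !is.null(genesets)) {
    universe <- rownames(tae)
    filtered <- stage("filter-sets",
                      filterSets(genesets, universe, minSetSize))
    res$binomial <- stage("binomial-enrichment", {
      lapply(res$topGenes, function(sel)
        binomialEnrichment(sel, filtered, universe, alpha = alpha))
    })
    for (pc in names(res$binomial))
      writeEnrichmentTsv(res$binomial[[pc]],
                         file.path(outDir,
                                   paste0("binomial_", pc, ".tsv")),
                         header = stamp)
    res$gsea <- stage("ranked-enrichment", {
      strains <- setdiff(unique(
        SummarizedExperiment::colData(tae)$strain), character(0))
      anc <- strains[1L]
      out <- list()
      for (s in setdiff(strains, anc)) {
        d <- makeDelta(profiles, paste0(s, "_r"), paste0(anc, "_r"),
                       name = paste0("dG_", s))
        out[[paste0("dG_", s)]] <-
          rankedEnrichment(d, filtered, nPerm = nPerm, seed = seed)
      }
      out
    })
    for (nm in names(res$gsea))
      writeEnrichmentTsv(res$gsea[[nm]],
                         file.path(outDir, paste0("gsea_", nm, ".tsv")),
                         header = stamp)
  } else {
    .log(logFile, "enrichment skipped")
  }

  res$epistasis <- stage("epistasis", {
    tab <- epistasisTable(profiles)
    if (!length(tab))
      stop("no evolved strain with heat-shock profiles")
    tab
  })
  epiDf <- epistasisAsDataFrame(res$epistasis)
  writeEnrichmentTsv(epiDf, file.path(outDir, "epistasis.tsv"),
                     header = stamp)

  summary <- list(
    tool = "ThermAdapt", version = .pkgVersion(),
    config = cfg, config_hash = .configHash(cfg), seed = seed,
    n_genes = nrow(tae), n_arrays = ncol(tae),
    profiles = profileLabels(profiles),
    variance_fraction = as.list(setNames(
      varianceFraction(res$pca),
      paste0("PC", seq_along(varianceFraction(res$pca))))),
    enrichment_skipped = skipEnrichment || is.null(genesets),
    epistasis = split(epiDf[setdiff(names(epiDf), "strain")],
                      epiDf$strain))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log(logFile, "pipeline complete: ", outDir)
  invisible(res)
}
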