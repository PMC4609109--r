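#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cor.test cutree hclust as.dist prcomp lm coef
#'   median pbinom rnorm rbinom runif sd var setNames p.adjust pt
#' @importFrom utils read.delim write.table head
NULL

.CONDITIONS <- c("r", "e", "hs")

#' Container for a thermal-adaptation array experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one assay
#' (`"exprs"`, log-scale expression, genes in rows and arrays in columns)
#' plus per-array metadata in `colData`: `strain`, `condition` (one of
#' `"r"` regular-temperature steady state, `"e"` evolution-temperature
#' steady state, `"hs"` heat shock), `replicate`, `temperature_C` and,
#' optionally, `growth_rate` (per hour).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("ThermalArrayExperiment", contains = "SummarizedExperiment")

setValidity("ThermalArrayExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!all(is.finite(v)))
      msg <- c(msg, "expression values must all be finite")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("strain", "condition", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (all(need %in% colnames(cd))) {
    if (!all(cd$condition %in% .CONDITIONS))
      msg <- c(msg, paste0("condition must be one of ",
                           paste(.CONDITIONS, collapse = "/")))
    key <- paste(cd$strain, cd$condition, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "(strain, condition, replicate) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Replicate-averaged expression profiles
#'
#' Genes x profiles matrix of replicate-averaged log expression, one
#' column per (strain, condition) pair labelled `"<strain>_<condition>"`
#' (e.g. `"41B_r"`, `"Anc_hs"`).
#'
#' @slot values numeric matrix, rownames are gene ids, colnames the labels.
#' @export
setClass("ProfileSet", representation(values = "matrix"))

setValidity("ProfileSet", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "profile labels (colnames) must be present and unique")
  if (!all(is.finite(v))) msg <- c(msg, "profile values must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-gene expression-change vector between two profiles
#'
#' @slot values named numeric vector of per-gene log-expression change.
#' @slot label contrast name, e.g. `"dG_41B"` or `"dHS_A"`.
#' @slot minuend,subtrahend the profile labels the contrast was built from.
#' @export
setClass("DeltaProfile",
         representation(values = "numeric", label = "character",
                        minuend = "character", subtrahend = "character"))

setValidity("DeltaProfile", function(object) {
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    return("delta values must be named by unique gene ids")
  TRUE
})

#' Principal component decomposition of expression profiles
#'
#' Columns (arrays or profiles) are the observations and genes the
#' variables; see [runPCA()].
#'
#' @slot scores observations x components matrix.
#' @slot loadings genes x components matrix with orthonormal columns; sign
#'   fixed so each column's largest-magnitude entry is positive.
#' @slot varianceFraction per-component fraction of total variance
#'   (non-increasing; sums to 1 over the full decomposition).
#' @slot center per-gene centering vector used (length 0 if uncentered).
#' @export
setClass("PCAResult",
         representation(scores = "matrix", loadings = "matrix",
                        varianceFraction = "numeric", center = "numeric"))

setValidity("PCAResult", function(object) {
  vf <- object@varianceFraction
  msg <- character()
  if (any(vf < -1e-12)) msg <- c(msg, "variance fractions must be >= 0")
  if (is.unsorted(rev(vf), strict = FALSE) && any(diff(vf) > 1e-10))
    msg <- c(msg, "variance fractions must be non-increasing")
  if (sum(vf) > 1 + 1e-8) msg <- c(msg, "variance fractions must sum to <= 1")
  if (ncol(object@loadings) != length(vf))
    msg <- c(msg, "loadings columns must match variance fractions")
  if (length(msg)) msg else TRUE
})

#' Named collection of gene sets
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot setType per-set annotation type tag (e.g. `"category"` or `"TF"`),
#'   recycled to the number of sets.
#' @slot source free-text provenance of the collection.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", setType = "character",
                        source = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "set names must be present and unique")
    if (any(!vapply(object@sets, is.character, logical(1))) ||
        any(vapply(object@sets, length, integer(1)) == 0L))
      msg <- c(msg, "each set must be a non-empty character vector")
  }
  if (length(object@setType) != length(object@sets))
    msg <- c(msg, "setType must have one entry per set")
  if (length(msg)) msg else TRUE
})

#' Negative-epistasis estimate for one evolved strain
#'
#' Ordinary least squares of the simultaneous expression change
#' (strain_hs - Anc_r) on the additive change (dG + dHS_A); the epistasis
#' magnitude is defined as `1 - slope`.
#'
#' @slot strain evolved strain label.
#' @slot nGenes number of genes entering the regression.
#' @slot r,rPvalue Pearson correlation between dHS_A and dG and its
#'   two-sided p-value.
#' @slot slope,intercept OLS fit of simultaneous on additive.
#' @slot magnitude `1 - slope`.
#' @slot subset gene-subset label (`"all"`, `"PC-top"`, or custom).
#' @export
setClass("EpistasisResult",
         representation(strain = "character", nGenes = "integer",
                        r = "numeric", rPvalue = "numeric",
                        slope = "numeric", intercept = "numeric",
                        magnitude = "numeric", subset = "character"))

setValidity("EpistasisResult", function(object) {
  msg <- character()
  if (object@nGenes < 3L) msg <- c(msg, "nGenes must be >= 3")
  if (abs(object@magnitude - (1 - object@slope)) > 1e-12)
    msg <- c(msg, "magnitude must equal 1 - slope")
  if (length(msg)) msg else TRUE
})

#' Ground-truth parameters of a synthetic dataset
#'
#' @slot baseline per-gene log-expression baseline.
#' @slot hsEffect per-gene heat-shock response (log units).
#' @slot genotypeEffect genes x strains cumulative mutation effects; the
#'   ancestor column is identically zero.
#' @slot tempEffect genes x strains evolution-temperature steady-state
#'   effects.
#' @slot hsRegulon gene ids of the planted heat-shock regulon.
#' @slot epistasisCoef scalar in [0, 1): fraction of the combined
#'   genotype + heat-shock effect cancelled in evolved strains.
#' @slot gtAnticorr target correlation between genotype and temperature
#'   effects (negative).
#' @slot noiseSd replicate noise standard deviation (log units).
#' @slot seed integer RNG seed the truth was drawn with.
#' @slot params full parameter list used by the generator.
#' @export
setClass("SyntheticTruth",
         representation(baseline = "numeric", hsEffect = "numeric",
                        genotypeEffect = "matrix", tempEffect = "matrix",
                        hsRegulon = "character", epistasisCoef = "numeric",
                        gtAnticorr = "numeric", noiseSd = "numeric",
                        seed = "integer", params = "list"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  e <- object@epistasisCoef
  if (length(e) != 1L || e < 0 || e >= 1)
    msg <- c(msg, "epistasisCoef must be a scalar in [0, 1)")
  strains <- colnames(object@genotypeEffect)
  if (is.null(strains))
    msg <- c(msg, "genotypeEffect must have strain colnames")
  else if (any(object@genotypeEffect[, 1L] != 0))
    msg <- c(msg, "ancestor (first strain) genotype effect must be zero")
  if (!identical(dim(object@genotypeEffect), dim(object@tempEffect)))
    msg <- c(msg, "genotypeEffect and tempEffect must be conformable")
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset bundle: expression, metadata, gene sets and truth
#'
#' @slot experiment the [ThermalArrayExperiment-class] with simulated
#'   expression and the sample sheet in `colData`.
#' @slot genesets a [GeneSetCollection-class].
#' @slot truth the [SyntheticTruth-class] the data were drawn from.
#' @export
setClass("SyntheticDataset",
         representation(experiment = "ThermalArrayExperiment",
                        genesets = "GeneSetCollection",
                        truth = "SyntheticTruth"))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  genes <- rownames(object@experiment)
  members <- unique(unlist(object@genesets@sets, use.names = FALSE))
  if (length(members) && !all(members %in% genes))
    msg <- c(msg, "all gene-set members must be genes of the experiment")
  if (length(msg)) msg else TRUE
})

#' Hierarchical clustering of expression profiles
#'
#' Wraps the agglomeration result together with the distance/linkage
#' configuration it was produced under.
#'
#' @slot hclust the [stats::hclust] tree.
#' @slot distance distance method used (`"pearson"` = 1 - Pearson r,
#'   `"spearman"` = 1 - Spearman rho, or `"euclidean"`).
#' @slot linkage agglomeration method (as in [stats::hclust()]).
#' @export
setClass("ProfileDendrogram",
         representation(hclust = "ANY", distance = "character",
                        linkage = "character"))
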