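# Accessor and show methods.

#' Construct a ThermalArrayExperiment
#'
#' @param exprs numeric matrix of log-scale expression, genes x arrays,
#'   with unique rownames (gene ids) and colnames (sample ids).
#' @param meta data.frame of per-array metadata with columns `sample_id`,
#'   `strain`, `condition`, `replicate` and optionally `temperature_C`
#'   and `growth_rate`; rows are matched to columns of `exprs` by
#'   `sample_id`.
#' @return a [ThermalArrayExperiment-class].
#' @examples
#' d <- generateDesign(1, 1, "Anc")
#' m <- matrix(rnorm(9), 3, 3,
#'             dimnames = list(paste0("g", 1:3), d$sample_id))
#' ThermalArrayExperiment(m, d)
#' @export
ThermalArrayExperiment <- function(exprs, meta) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("'exprs' must be a numeric matrix")
  if (!is.data.frame(meta) || !"sample_id" %in% colnames(meta))
    stop("'meta' must be a data.frame with a sample_id column")
  missing <- setdiff(colnames(exprs), meta$sample_id)
  if (length(missing))
    stop("samples lacking metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(exprs), meta$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(meta[setdiff(colnames(meta), "sample_id")],
                             row.names = meta$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  methods::new("ThermalArrayExperiment", se)
}

#' Expression values of a ThermalArrayExperiment
#'
#' @param x a [ThermalArrayExperiment-class].
#' @return the genes x arrays log-expression matrix.
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' Sample metadata as a plain data.frame
#'
#' @param x a [ThermalArrayExperiment-class].
#' @return data.frame with a `sample_id` column followed by the colData
#'   columns.
#' @export
sampleMeta <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(sample_id = rownames(cd), cd, row.names = NULL,
             check.names = FALSE)
}

#' @rdname accessors
setMethod("geneIds", "ThermalArrayExperiment", function(x) rownames(x))
#' @rdname accessors
setMethod("geneIds", "ProfileSet", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "DeltaProfile", function(x) names(x@values))
#' @rdname accessors
setMethod("geneIds", "SyntheticTruth", function(x) names(x@baseline))

#' @rdname accessors
setMethod("profileLabels", "ProfileSet", function(x) colnames(x@values))
#' @rdname accessors
setMethod("profileValues", "ProfileSet", function(x) x@values)
#' @rdname accessors
setMethod("deltaValues", "DeltaProfile", function(x) x@values)

#' @rdname accessors
setMethod("pcaScores", "PCAResult", function(x) x@scores)
#' @rdname accessors
setMethod("pcaLoadings", "PCAResult", function(x) x@loadings)
#' @rdname accessors
setMethod("varianceFraction", "PCAResult", function(x) x@varianceFraction)

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @rdname accessors
setMethod("geneSets", "SyntheticDataset", function(x) x@genesets@sets)
#' @rdname accessors
setMethod("truth", "SyntheticDataset", function(x) x@truth)
#' @rdname accessors
setMethod("experiment", "SyntheticDataset", function(x) x@experiment)

setMethod("show", "ProfileSet", function(object) {
  v <- object@values
  cat("ProfileSet with", nrow(v), "genes x", ncol(v), "profiles\n")
  cat("profiles:", paste(colnames(v), collapse = " "), "\n")
})

setMethod("show", "DeltaProfile", function(object) {
  cat("DeltaProfile", object@label, "=", object@minuend, "-",
      object@subtrahend, "(", length(object@values), "genes )\n")
})

setMethod("show", "PCAResult", function(object) {
  k <- length(object@varianceFraction)
  cat("PCAResult:", nrow(object@scores), "observations,",
      nrow(object@loadings), "genes,", k, "components\n")
  cat("variance fractions:",
      paste(sprintf("%s=%.3f", colnames(object@loadings),
                    object@varianceFraction), collapse = " "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  n <- length(object@sets)
  cat("GeneSetCollection with", n, "sets")
  if (n) {
    sz <- vapply(object@sets, length, integer(1))
    cat(" (sizes ", min(sz), "-", max(sz), ")", sep = "")
  }
  cat("; source:", object@source, "\n")
})

setMethod("show", "EpistasisResult", function(object) {
  cat(sprintf(
    "EpistasisResult %s [%s]: slope=%.3f magnitude=%.3f (n=%d, r=%.3f)\n",
    object@strain, object@subset, object@slope, object@magnitude,
    object@nGenes, object@r))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@baseline), "genes,",
      ncol(object@genotypeEffect), "strains; epistasisCoef =",
      object@epistasisCoef, "; gtAnticorr =", object@gtAnticorr,
      "; noiseSd =", object@noiseSd, "; seed =", object@seed, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset\n")
  methods::show(object@experiment)
  methods::show(object@genesets)
})

setMethod("show", "ProfileDendrogram", function(object) {
  cat("ProfileDendrogram (", object@distance, "distance,",
      object@linkage, "linkage ) over",
      length(object@hclust$labels), "profiles\n")
})

#' Coerce an EpistasisResult (or list of them) to a data.frame
#'
#' @param x an [EpistasisResult-class] or a list of them.
#' @return one row per result with columns strain, subset, n_genes, r,
#'   r_pvalue, slope, intercept, magnitude.
#' @export
epistasisAsDataFrame <- function(x) {
  if (methods::is(x, "EpistasisResult")) x <- list(x)
  do.call(rbind, lapply(x, function(e) {
    data.frame(strain = e@strain, subset = e@subset, n_genes = e@nGenes,
               r = e@r, r_pvalue = e@rPvalue, slope = e@slope,
               intercept = e@intercept, magnitude = e@magnitude)
  }))
}
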