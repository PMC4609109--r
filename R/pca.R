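# PCA of expression profiles: variance accounting, loading-based gene
# selection, PC-growth-rate association.

#' Principal component analysis of expression columns
#'
#' Arrays (or replicate-averaged profiles) are the observations and genes
#' the variables, so components capture expression variance between the
#' culturing conditions. Covariance PCA (gene-wise centering, no
#' unit-variance scaling) is used: scaling each gene would discard the
#' magnitude structure that links the leading component to growth.
#' The decomposition is deterministic up to sign; signs are fixed so that
#' each loading column's largest-magnitude entry is positive.
#'
#' @param x genes x columns numeric matrix, [ThermalArrayExperiment-class]
#'   or [ProfileSet-class].
#' @param nComponents number of components to keep (default: full rank).
#' @param center gene-wise centering flag (default TRUE).
#' @param ... unused.
#' @return a [PCAResult-class]. Variance fractions are relative to the
#'   total variance of the full decomposition, so they sum to 1 only
#'   when all components are kept.
#' @rdname runPCA
#' @export
setMethod("runPCA", "matrix", function(x, nComponents = NULL,
                                       center = TRUE, ...) {
  if (ncol(x) < 2L) stop("need at least 2 columns")
  full <- min(nrow(x), ncol(x) - as.integer(center))
  if (is.null(nComponents)) nComponents <- full
  if (nComponents > full)
    stop("nComponents exceeds the rank bound (", full, ")")
  p <- prcomp(t(x), center = center, scale. = FALSE)
  ev <- p$sdev^2
  vf <- ev / sum(ev)
  k <- nComponents
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  methods::new("PCAResult", scores = scores, loadings = loadings,
               varianceFraction = vf[seq_len(k)],
               center = if (center) p$center else numeric(0))
})

#' @rdname runPCA
setMethod("runPCA", "ThermalArrayExperiment",
          function(x, nComponents = NULL, center = TRUE, ...)
            runPCA(exprsValues(x), nComponents, center))

#' @rdname runPCA
setMethod("runPCA", "ProfileSet",
          function(x, nComponents = NULL, center = TRUE, ...)
            runPCA(profileValues(x), nComponents, center))

#' Genes most heavily loaded on a component
#'
#' Takes the union of the `ceiling(alpha * N)` most positively and
#' `floor(alpha * N)` most negatively loaded genes (`alpha` =
#' `tailFraction`, `N` = gene count). With this rounding a 4383-gene
#' matrix at the default 5% yields exactly 439 genes per component.
#' Ties are broken by gene id order, deterministically.
#'
#' @param pca a [PCAResult-class].
#' @param component component label (e.g. `"PC1"`).
#' @param tailFraction fraction per tail, in (0, 0.5).
#' @return character vector of selected gene ids (positive tail first,
#'   each tail ordered by decreasing |loading|).
#' @export
topLoadedGenes <- function(pca, component, tailFraction = 0.05) {
  if (tailFraction <= 0 || tailFraction >= 0.5)
    stop("tailFraction must lie in (0, 0.5)")
  L <- pcaLoadings(pca)
  if (!component %in% colnames(L))
    stop("unknown component: ", component)
  v <- L[, component]
  genes <- rownames(L)
  n <- length(v)
  nPos <- ceiling(tailFraction * n)
  nNeg <- floor(tailFraction * n)
  ordPos <- order(-v, genes)
  ordNeg <- order(v, genes)
  c(genes[ordPos[seq_len(nPos)]], genes[ordNeg[seq_len(nNeg)]])
}

#' Correlation between component scores and growth rates
#'
#' @param pca a [PCAResult-class] computed on individual arrays (or
#'   profiles whose labels match `names(growthRates)`).
#' @param growthRates named numeric vector of per-observation growth
#'   rates, or a [ThermalArrayExperiment-class] whose colData carries a
#'   `growth_rate` column.
#' @param component component label (default `"PC1"`).
#' @return Pearson correlation coefficient.
#' @export
pcGrowthCorrelation <- function(pca, growthRates, component = "PC1") {
  if (methods::is(growthRates, "ThermalArrayExperiment")) {
    cd <- SummarizedExperiment::colData(growthRates)
    if (!"growth_rate" %in% colnames(cd))
      stop("experiment colData has no growth_rate column")
    growthRates <- setNames(cd$growth_rate, rownames(cd))
  }
  s <- pcaScores(pca)
  if (!component %in% colnames(s)) stop("unknown component: ", component)
  obs <- rownames(s)
  miss <- obs[!obs %in% names(growthRates) |
                is.na(growthRates[obs])]
  if (length(miss))
    stop("missing growth rates for: ", paste(miss, collapse = ", "))
  g <- growthRates[obs]
  if (sd(g) == 0) stop("correlation undefined: constant growth rates")
  cor(s[, component], g)
}

#' Write PCA outputs as TSV
#'
#' Writes `scores.tsv`, `loadings.tsv` and `variance.tsv` into `dir`.
#'
#' @param pca a [PCAResult-class].
#' @param dir output directory.
#' @param header optional comment lines.
#' @return named vector of paths, invisibly.
#' @export
writePcaTsv <- function(pca, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(m, path, rowlab) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    writeLines(paste(c(rowlab, colnames(m)), collapse = "\t"), con)
    writeLines(paste(rownames(m),
                     apply(m, 1L, function(v)
                       paste(format(v, digits = 15, trim = TRUE),
                             collapse = "\t")), sep = "\t"), con)
  }
  paths <- c(scores = file.path(dir, "scores.tsv"),
             loadings = file.path(dir, "loadings.tsv"),
             variance = file.path(dir, "variance.tsv"))
  wt(pcaScores(pca), paths[["scores"]], "observation")
  wt(pcaLoadings(pca), paths[["loadings"]], "gene_id")
  vf <- varianceFraction(pca)
  wt(matrix(vf, ncol = 1,
            dimnames = list(paste0("PC", seq_along(vf)), "fraction")),
     paths[["variance"]], "component")
  invisible(paths)
}
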