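# Profile-level comparisons: correlations, condition dendrogram,
# contrast (delta) construction and gene-set delta summaries.

.profileColumn <- function(profiles, label) {
  v <- profileValues(profiles)
  if (!label %in% colnames(v))
    stop("unknown profile label: ", label)
  v[, label]
}

.corMethod <- function(method) {
  method <- match.arg(method, c("pearson", "spearman"))
  method
}

#' Correlation between two expression profiles
#'
#' @param profiles a [ProfileSet-class].
#' @param a,b profile labels.
#' @param method `"pearson"` (default; the log-log scatter convention) or
#'   `"spearman"`.
#' @return correlation coefficient in [-1, 1].
#' @export
profileCorrelation <- function(profiles, a, b, method = "pearson") {
  method <- .corMethod(method)
  x <- .profileColumn(profiles, a)
  y <- .profileColumn(profiles, b)
  if (length(x) < 3L) stop("need at least 3 genes")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero-variance profile")
  cor(x, y, method = method)
}

#' All pairwise profile correlations
#'
#' @inheritParams profileCorrelation
#' @return symmetric labelled correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(profiles, method = "pearson") {
  method <- .corMethod(method)
  v <- profileValues(profiles)
  if (ncol(v) < 2L) stop("need at least 2 profiles")
  if (any(apply(v, 2L, sd) == 0))
    stop("correlation undefined: zero-variance profile")
  cor(v, method = method)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of the profile columns under a correlation
#' distance (default `1 - Pearson r`) with average linkage. Profiles are
#' ordered lexicographically by label before agglomeration so ties are
#' broken deterministically.
#'
#' @inheritParams profileCorrelation
#' @param distance `"pearson"`, `"spearman"` (both as `1 - correlation`)
#'   or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return a [ProfileDendrogram-class].
#' @export
clusterProfiles <- function(profiles, distance = "pearson",
                            linkage = "average") {
  v <- profileValues(profiles)
  if (ncol(v) < 2L) stop("need at least 2 profiles")
  distance <- match.arg(distance, c("pearson", "spearman", "euclidean"))
  v <- v[, order(colnames(v)), drop = FALSE]
  d <- if (distance == "euclidean") stats::dist(t(v))
       else as.dist(1 - cor(v, method = distance))
  h <- tryCatch(hclust(d, method = linkage),
                error = function(e) stop("invalid linkage method: ",
                                         linkage))
  methods::new("ProfileDendrogram", hclust = h, distance = distance,
               linkage = linkage)
}

#' Dendrogram as an ape phylogeny / Newick string
#'
#' Branch lengths derive from the merge heights of the agglomeration.
#'
#' @param dend a [ProfileDendrogram-class].
#' @return `dendrogramPhylo`: an [ape::as.phylo] tree;
#'   `dendrogramNewick`: a Newick string (written to `path` if given).
#' @export
dendrogramPhylo <- function(dend) ape::as.phylo(dend@hclust)

#' @param path optional output file for the Newick string.
#' @rdname dendrogramPhylo
#' @export
dendrogramNewick <- function(dend, path = NULL) {
  phy <- dendrogramPhylo(dend)
  if (is.null(path)) ape::write.tree(phy)
  else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Leaf groups at the first split of a dendrogram
#'
#' @param dend a [ProfileDendrogram-class].
#' @param k number of groups to cut into (default 2, the first split).
#' @return list of character vectors of profile labels, one per group.
#' @export
dendrogramSplit <- function(dend, k = 2L) {
  ct <- cutree(dend@hclust, k = k)
  unname(split(names(ct), ct))
}

#' Construct a contrast (delta profile) between two profiles
#'
#' Element-wise `minuend - subtrahend` on the log scale.
#'
#' @param profiles a [ProfileSet-class].
#' @param minuend,subtrahend profile labels.
#' @param name contrast label; defaults to `"<minuend>-<subtrahend>"`.
#' @return a [DeltaProfile-class].
#' @export
makeDelta <- function(profiles, minuend, subtrahend, name = NULL) {
  x <- .profileColumn(profiles, minuend)
  y <- .profileColumn(profiles, subtrahend)
  methods::new("DeltaProfile", values = x - y,
               label = name %||% paste0(minuend, "-", subtrahend),
               minuend = minuend, subtrahend = subtrahend)
}

#' Standard contrasts for one strain
#'
#' The four named contrasts of the analysis, all against the ancestor's
#' regular-temperature steady state:
#' * `dG`: genotype-mediated change, `strain_r - Anc_r`;
#' * `dHS_A`: heat-shock-induced change in the ancestor,
#'   `Anc_hs - Anc_r`;
#' * `dT`: growth-temperature-mediated change, `strain_e - strain_r`;
#' * `dGHS`: simultaneous change, `strain_hs - Anc_r`.
#'
#' @param profiles a [ProfileSet-class].
#' @param strain strain label.
#' @param ancestor ancestor label (default `"Anc"`).
#' @return named list of [DeltaProfile-class] objects.
#' @export
standardContrasts <- function(profiles, strain, ancestor = "Anc") {
  ar <- paste0(ancestor, "_r")
  list(
    dG    = makeDelta(profiles, paste0(strain, "_r"), ar,
                      name = paste0("dG_", strain)),
    dHS_A = makeDelta(profiles, paste0(ancestor, "_hs"), ar,
                      name = "dHS_A"),
    dT    = makeDelta(profiles, paste0(strain, "_e"),
                      paste0(strain, "_r"), name = paste0("dT_", strain)),
    dGHS  = makeDelta(profiles, paste0(strain, "_hs"), ar,
                      name = paste0("dGHS_", strain)))
}

#' Summarize a contrast over a gene set
#'
#' Used e.g. to verify that heat-shock genes show equivalent induction
#' across strains, and that their expression returns toward the steady
#' level at evolved steady states.
#'
#' @param delta a [DeltaProfile-class].
#' @param geneset character vector of gene ids; at least one must be
#'   present in the delta.
#' @return list with elements `mean`, `median` and `n` (set members
#'   found).
#' @export
genesetDeltaSummary <- function(delta, geneset) {
  v <- deltaValues(delta)
  hit <- intersect(geneset, names(v))
  if (!length(hit))
    stop("no gene-set member present in the delta profile")
  list(mean = mean(v[hit]), median = median(v[hit]), n = length(hit))
}

#' Write a correlation matrix or delta profile as TSV
#'
#' @param x correlation matrix or [DeltaProfile-class].
#' @param path output file.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
writeComparativeTsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  if (methods::is(x, "DeltaProfile")) {
    writeLines(paste("gene_id", x@label, sep = "\t"), con)
    writeLines(paste(names(x@values),
                     format(x@values, digits = 15, trim = TRUE),
                     sep = "\t"), con)
  } else {
    writeLines(paste(c("profile", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x),
                     apply(x, 1L, function(v)
                       paste(format(v, digits = 15, trim = TRUE),
                             collapse = "\t")), sep = "\t"), con)
  }
  invisible(path)
}
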