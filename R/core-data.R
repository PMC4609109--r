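# File I/O, normalization, replicate averaging and growth-rate arithmetic.

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers and a tab-separated numeric body. Duplicated identifiers,
#' non-numeric cells and ragged rows are hard errors: the array pipeline
#' this package targets produces complete matrices, and silent imputation
#' would corrupt every downstream contrast.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene ids as rownames, sample ids as
#'   colnames; row and column order as on file.
#' @export
readExpressionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop("ragged row at line ", which(nf != nf[1L])[1L], " of ", path)
  samples <- fields[[1L]][-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample id in header of ", path)
  body <- fields[-1L]
  genes <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    bad <- which(duplicated(genes))[1L] + 1L
    stop("duplicated gene id at line ", bad, " of ", path)
  }
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    v
  }, numeric(length(samples)))
  vals <- matrix(vals, nrow = length(samples))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 2L, anyNA))[1L] + 1L
    stop("non-numeric cell at line ", bad, " of ", path)
  }
  m <- t(vals)
  dimnames(m) <- list(genes, samples)
  m
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix (genes x samples) with dimnames, a
#'   [ThermalArrayExperiment-class] or a [ProfileSet-class].
#' @param path output file.
#' @param header optional comment lines (prefixed `#`) written before the
#'   table.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, header = NULL) {
  if (methods::is(x, "ThermalArrayExperiment")) x <- exprsValues(x)
  if (methods::is(x, "ProfileSet")) x <- profileValues(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `strain`,
#' `condition`, `replicate`, `temperature_C` and optionally
#' `growth_rate`.
#'
#' @param path file path.
#' @return `readSampleSheet`: a data.frame.
#' @export
readSampleSheet <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c("sample_id", "strain", "condition", "replicate")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' @param meta data.frame as produced by [generateDesign()].
#' @param header optional comment lines.
#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(meta, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(meta, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the expression table of a GEO Series Matrix file
#'
#' Parses the table between the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` delimiters of a GEO Series Matrix text
#' file, and captures `!Sample_title` / `!Sample_geo_accession` headers
#' so the user can map array titles onto strain/condition labels.
#' Values are passed through untransformed: GEO deposits differ in log
#' base and normalization, and that interpretation is left to the caller.
#'
#' @param path path to a (uncompressed) series matrix file.
#' @return list with elements `exprs` (numeric matrix, ID_REF rownames,
#'   accession colnames) and `meta` (data.frame with `sample_id` and
#'   `title`).
#' @export
readGeoSeriesMatrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("series-matrix table delimiters not found in ", path)
  strip <- function(x) gsub('^"|"$', "", x)
  tab <- strsplit(lines[(beg + 1L):(end - 1L)], "\t", fixed = TRUE)
  header <- strip(tab[[1L]])
  ids <- vapply(tab[-1L], function(f) strip(f[1L]), character(1))
  vals <- t(vapply(tab[-1L],
                   function(f) suppressWarnings(as.numeric(strip(f[-1L]))),
                   numeric(length(header) - 1L)))
  if (length(header) == 2L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(ids, header[-1L])
  titles <- grep("^!Sample_title", lines, value = TRUE)
  meta <- data.frame(sample_id = colnames(vals),
                     title = rep(NA_character_, ncol(vals)))
  if (length(titles) == 1L) {
    tt <- strip(strsplit(titles, "\t", fixed = TRUE)[[1L]][-1L])
    if (length(tt) == ncol(vals)) meta$title <- tt
  }
  list(exprs = vals, meta = meta)
}

#' Global median normalization
#'
#' Subtracts each array's median log expression so that every column has
#' median exactly zero. This is the standard "global normalization" for
#' log-scale array data and is idempotent; within-column rank order is
#' unchanged.
#'
#' @param x numeric matrix, [ThermalArrayExperiment-class] or
#'   [ProfileSet-class].
#' @param ... unused.
#' @return object of the same class with median-zero columns.
#' @examples
#' globalNormalize(cbind(s1 = c(1, 2, 3)))  # -> -1, 0, 1
#' @rdname globalNormalize
#' @export
setMethod("globalNormalize", "matrix", function(x, ...) {
  if (!length(x)) stop("cannot normalize an empty matrix")
  meds <- apply(x, 2L, median)
  sweep(x, 2L, meds)
})

#' @rdname globalNormalize
setMethod("globalNormalize", "ThermalArrayExperiment", function(x, ...) {
  SummarizedExperiment::assay(x, "exprs") <-
    globalNormalize(exprsValues(x))
  x
})

#' @rdname globalNormalize
setMethod("globalNormalize", "ProfileSet", function(x, ...) {
  methods::new("ProfileSet", values = globalNormalize(x@values))
})

#' Average biological replicates into condition profiles
#'
#' Collapses arrays to one column per (strain, condition) pair by the
#' arithmetic mean over replicates, labelled `"<strain>_<condition>"`.
#' Strains keep their order of first appearance in the metadata;
#' conditions are ordered r, e, hs.
#'
#' @param x a [ThermalArrayExperiment-class].
#' @return a [ProfileSet-class].
#' @export
averageReplicates <- function(x) {
  stopifnot(methods::is(x, "ThermalArrayExperiment"))
  cd <- SummarizedExperiment::colData(x)
  strains <- unique(as.character(cd$strain))
  conds <- intersect(.CONDITIONS, unique(as.character(cd$condition)))
  v <- exprsValues(x)
  cols <- list()
  for (s in strains) for (cc in conds) {
    idx <- which(cd$strain == s & cd$condition == cc)
    if (length(idx))
      cols[[paste0(s, "_", cc)]] <- rowMeans(v[, idx, drop = FALSE])
  }
  methods::new("ProfileSet", values = do.call(cbind, cols))
}

#' Exponential growth rate from endpoint cell concentrations
#'
#' `log(nf / n0) / hours`, the per-hour exponential rate implied by the
#' initial and final cell concentrations and the culturing time.
#'
#' @param n0,nf initial and final cell concentrations (cells/ml), > 0.
#' @param hours culturing time in hours, > 0.
#' @return growth rate in 1/h.
#' @examples
#' growthRate(1e4, 2e8, 14)  # ~0.707 per hour
#' @export
growthRate <- function(n0, nf, hours) {
  if (any(n0 <= 0) || any(nf <= 0) || any(hours <= 0))
    stop("n0, nf and hours must all be positive")
  log(nf / n0) / hours
}
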