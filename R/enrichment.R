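# Gene-set enrichment: GMT I/O, size filtering, exact binomial
# over-representation tests, and a ranked running-sum statistic with
# gene-label-permutation significance.

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated. The description field carries the set-type tag on
#' write and is parsed back into `setType` on read when it matches a
#' known tag.
#'
#' @param path GMT file path.
#' @param setType default type tag for sets whose description is not a
#'   recognized tag.
#' @return `readGmt`: a [GeneSetCollection-class].
#' @export
readGmt <- function(path, setType = "category") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields in ", path)
  nm <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  types <- ifelse(desc %in% c("category", "TF"), desc, setType)
  methods::new("GeneSetCollection", sets = sets, setType = types,
               source = path)
}

#' @param collection a [GeneSetCollection-class].
#' @rdname readGmt
#' @export
writeGmt <- function(collection, path) {
  lines <- vapply(seq_along(collection@sets), function(i)
    paste(c(names(collection@sets)[i], collection@setType[i],
            collection@sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to a universe and drop small sets
#'
#' Members are intersected with the universe; sets whose intersected
#' size is not strictly greater than `minSize - 1` are removed (the
#' default keeps sets with more than 15 in-universe genes).
#'
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector of gene ids.
#' @param minSize smallest retained intersected size (default 16).
#' @return filtered [GeneSetCollection-class] (possibly empty).
#' @export
filterSets <- function(collection, universe, minSize = 16L) {
  if (!length(universe)) stop("universe must be non-empty")
  sets <- lapply(collection@sets, intersect, universe)
  keep <- vapply(sets, length, integer(1)) >= minSize
  methods::new("GeneSetCollection", sets = sets[keep],
               setType = collection@setType[keep],
               source = collection@source)
}

#' Exact binomial over-representation test per gene set
#'
#' For each set of (in-universe) size K in a universe of N genes and a
#' selection of n genes with k overlapping the set, the one-sided
#' (greater) p-value is the exact binomial tail
#' `P(X >= k), X ~ Binomial(n, K/N)`. Bonferroni adjustment multiplies
#' by the number of tested sets.
#'
#' @param selected character vector of selected genes; must be a subset
#'   of the universe.
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector of gene ids.
#' @param alternative `"greater"` (default; enrichment) or
#'   `"two.sided"` (doubles the smaller tail, capped at 1).
#' @param alpha significance threshold applied to the Bonferroni-adjusted
#'   p (default 0.001).
#' @return data.frame with one row per set: `set`, `type`, `n_set`,
#'   `n_hit`, `expected`, `p`, `bonferroni`, `log10p` (of the adjusted
#'   value) and `significant`.
#' @export
binomialEnrichment <- function(selected, collection, universe,
                               alternative = c("greater", "two.sided"),
                               alpha = 0.001) {
  alternative <- match.arg(alternative)
  off <- setdiff(selected, universe)
  if (length(off))
    stop("selected genes outside the universe: ",
         paste(head(off, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(selected)
  sets <- lapply(collection@sets, intersect, universe)
  m <- length(sets)
  rows <- lapply(seq_len(m), function(i) {
    K <- length(sets[[i]])
    k <- length(intersect(selected, sets[[i]]))
    pr <- K / N
    pUp <- pbinom(k - 1L, n, pr, lower.tail = FALSE)
    p <- if (alternative == "greater") pUp
         else min(1, 2 * min(pUp, pbinom(k, n, pr)))
    data.frame(set = names(sets)[i], type = collection@setType[i],
               n_set = K, n_hit = k, expected = n * pr, p = p)
  })
  out <- do.call(rbind, rows)
  out$bonferroni <- pmin(1, out$p * m)
  out$log10p <- log10(pmax(out$bonferroni, .Machine$double.xmin))
  out$significant <- out$bonferroni < alpha
  out[order(out$p), , drop = FALSE]
}

# Weighted Kolmogorov-Smirnov-style running-sum enrichment score.
# `positions`: sorted rank positions of the set members (1 = top of the
# ranking); `weights`: |delta|^exponent in ranking order (length N).
# Member steps increment by their weight share; non-members decrement by
# 1/(N-K). The ES is the maximum absolute deviation of the running sum,
# with its sign. Extrema can only occur immediately after a member step
# (candidate maxima) or immediately before one (candidate minima), which
# is what is enumerated here.
.runningSumES <- function(positions, weights) {
  N <- length(weights)
  K <- length(positions)
  if (K == 0L || K == N) stop("set must be a proper subset of the ranking")
  positions <- sort(positions)
  w <- weights[positions]
  NR <- sum(w)
  if (NR == 0) w[] <- 1 / K else w <- w / NR
  cw <- cumsum(w)
  missStep <- 1 / (N - K)
  nMissBefore <- positions - seq_len(K)
  after <- cw - nMissBefore * missStep
  before <- c(0, cw[-K]) - nMissBefore * missStep
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Genes are ranked by decreasing score; set members contribute
#' increments proportional to `|score|^weightExponent` (equal steps when
#' the exponent is 0) and non-members a constant decrement. The ES is
#' the maximum absolute deviation of the running sum, signed.
#'
#' @param scores named numeric vector (the ranking metric, e.g. a delta
#'   profile's values).
#' @param geneset character vector of member gene ids.
#' @param weightExponent weighting exponent (default 1).
#' @return the enrichment score in [-1, 1].
#' @export
enrichmentScore <- function(scores, geneset, weightExponent = 1) {
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  w <- abs(scores[ord])^weightExponent
  pos <- which(ranked %in% geneset)
  .runningSumES(pos, w)
}

#' Ranked gene-set enrichment with permutation significance
#'
#' Genes are ranked by a contrast (descending); each set's enrichment
#' score is the signed maximum deviation of a weighted running sum (see
#' [enrichmentScore()]). Significance comes from gene-label permutations:
#' sample permutations are degenerate with 2-3 replicates per condition,
#' so `nPerm` random same-size member sets form the null. The normalized
#' score (NES) divides the ES by the mean absolute null ES of matching
#' sign, the permutation p compares against same-signed nulls, and FDR q
#' uses the positive/negative NES ratio method. Direction is `"up"` when
#' the set is enriched among up-regulated genes (ES > 0), else `"down"`.
#'
#' @param delta a [DeltaProfile-class] or named numeric ranking metric.
#' @param collection a [GeneSetCollection-class] (filter with
#'   [filterSets()] first; members are intersected with the ranking).
#' @param weightExponent running-sum weight exponent (default 1).
#' @param nPerm number of gene-label permutations (default 1000; fewer
#'   than 100 triggers a warning).
#' @param seed optional RNG seed for the permutation stream.
#' @return data.frame with columns `set`, `type`, `size`, `ES`, `NES`,
#'   `p`, `q`, `direction`, sorted by p.
#' @export
rankedEnrichment <- function(delta, collection, weightExponent = 1,
                             nPerm = 1000L, seed = NULL) {
  scores <- if (methods::is(delta, "DeltaProfile")) deltaValues(delta)
            else delta
  if (!length(scores)) stop("zero-length ranking")
  if (nPerm < 100L)
    warning("nPerm < 100 gives a very coarse permutation null")
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  w <- abs(scores[ord])^weightExponent
  N <- length(ranked)
  sets <- lapply(collection@sets, function(s)
    which(ranked %in% s))
  keep <- vapply(sets, function(p) length(p) >= 1L && length(p) < N,
                 logical(1))
  if (!any(keep)) stop("no usable gene set after intersection")
  sets <- sets[keep]
  types <- collection@setType[keep]
  run <- function() {
    es <- vapply(sets, .runningSumES, numeric(1), weights = w)
    sizes <- vapply(sets, length, integer(1))
    # one shared null per distinct set size
    nullES <- lapply(unique(sizes), function(K) {
      vapply(seq_len(nPerm), function(b)
        .runningSumES(sample.int(N, K), w), numeric(1))
    })
    names(nullES) <- as.character(unique(sizes))
    nes <- numeric(length(es))
    pval <- numeric(length(es))
    nesNull <- vector("list", length(es))
    for (i in seq_along(es)) {
      nul <- nullES[[as.character(sizes[i])]]
      posMean <- mean(nul[nul > 0])
      negMean <- mean(abs(nul[nul < 0]))
      same <- nul[sign(nul) == sign(es[i])]
      pval[i] <- if (!length(same)) 1 / (nPerm + 1)
                 else sum(abs(same) >= abs(es[i])) / length(same)
      denom <- if (es[i] >= 0) posMean else negMean
      if (!is.finite(denom) || denom == 0) denom <- mean(abs(nul))
      nes[i] <- if (denom == 0) 0 else es[i] / denom
      nn <- ifelse(nul >= 0,
                   nul / (if (is.finite(posMean) && posMean > 0)
                            posMean else mean(abs(nul))),
                   nul / (if (is.finite(negMean) && negMean > 0)
                            negMean else mean(abs(nul))))
      nesNull[[i]] <- nn
    }
    # positive/negative ratio FDR on NES
    pooled <- unlist(nesNull, use.names = FALSE)
    q <- vapply(seq_along(es), function(i) {
      v <- nes[i]
      if (v >= 0) {
        nullFrac <- mean(pooled[pooled >= 0] >= v)
        obsFrac <- mean(nes[nes >= 0] >= v)
      } else {
        nullFrac <- mean(pooled[pooled <= 0] <= v)
        obsFrac <- mean(nes[nes <= 0] <= v)
      }
      if (is.nan(nullFrac) || is.nan(obsFrac) || obsFrac == 0) 1
      else min(1, nullFrac / obsFrac)
    }, numeric(1))
    data.frame(set = names(sets), type = types,
               size = vapply(sets, length, integer(1)),
               ES = es, NES = nes, p = pval, q = q,
               direction = ifelse(es > 0, "up", "down"))
  }
  out <- if (is.null(seed)) run() else .withSeed(seed, run())
  out[order(out$p, -abs(out$NES)), , drop = FALSE]
}

#' Write an enrichment table as TSV
#'
#' @param x data.frame from [binomialEnrichment()] or
#'   [rankedEnrichment()].
#' @param path output file.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
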