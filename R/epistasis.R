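# Negative-epistasis decomposition: genotype-mediated vs
# heat-shock-induced expression change, and 1 - slope of simultaneous on
# additive change.

#' Contrasts entering the epistasis analysis for one strain
#'
#' Builds the genotype-mediated change `dG = strain_r - Anc_r`, the
#' ancestral heat-shock-induced change `dHS_A = Anc_hs - Anc_r`, their
#' sum (`additive`) and the simultaneous change
#' `dGHS = strain_hs - Anc_r`.
#'
#' @param profiles a [ProfileSet-class] containing `Anc_r`, `Anc_hs`,
#'   `<strain>_r` and `<strain>_hs`.
#' @param strain evolved strain label.
#' @param ancestor ancestor label (default `"Anc"`).
#' @return named list of [DeltaProfile-class]: `dG`, `dHS_A`, `additive`,
#'   `simultaneous`.
#' @export
epistasisContrasts <- function(profiles, strain, ancestor = "Anc") {
  need <- c(paste0(ancestor, c("_r", "_hs")),
            paste0(strain, c("_r", "_hs")))
  have <- profileLabels(profiles)
  miss <- setdiff(need, have)
  if (length(miss))
    stop("missing profile(s): ", paste(miss, collapse = ", "))
  ar <- paste0(ancestor, "_r")
  dG <- makeDelta(profiles, paste0(strain, "_r"), ar,
                  name = paste0("dG_", strain))
  dHS <- makeDelta(profiles, paste0(ancestor, "_hs"), ar, name = "dHS_A")
  add <- methods::new("DeltaProfile",
                      values = deltaValues(dG) + deltaValues(dHS),
                      label = paste0("additive_", strain),
                      minuend = paste0(strain, "_r+", ancestor, "_hs"),
                      subtrahend = paste0("2x", ar))
  sim <- makeDelta(profiles, paste0(strain, "_hs"), ar,
                   name = paste0("dGHS_", strain))
  list(dG = dG, dHS_A = dHS, additive = add, simultaneous = sim)
}

#' Correlation between two contrasts
#'
#' Pearson r with a two-sided p-value from the t distribution on n - 2
#' degrees of freedom.
#'
#' @param x,y [DeltaProfile-class] objects over the same genes.
#' @return list with elements `r` and `p`.
#' @export
deltaAssociation <- function(x, y) {
  vx <- deltaValues(x)
  vy <- deltaValues(y)
  if (!identical(names(vx), names(vy))) {
    common <- intersect(names(vx), names(vy))
    if (length(common) != length(vx) || length(common) != length(vy))
      stop("delta profiles cover different gene sets")
    vy <- vy[names(vx)]
  }
  if (length(vx) < 3L) stop("need at least 3 genes")
  if (sd(vx) == 0 || sd(vy) == 0)
    stop("correlation undefined: zero-variance contrast")
  ct <- cor.test(vx, vy, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Negative epistasis as 1 - slope of simultaneous on additive change
#'
#' Ordinary least squares of the simultaneous change on the additive
#' change, with a free intercept by default; the epistasis magnitude is
#' `1 - slope` (0 = purely additive, positive = cancellation). A
#' through-origin fit is available. An optional gene subset implements
#' the analysis restricted to e.g. the top PC-loaded genes.
#'
#' @param additive,simultaneous [DeltaProfile-class] objects over the
#'   same genes.
#' @param genes optional character vector restricting the regression.
#' @param strain strain label recorded in the result.
#' @param subsetLabel label recorded for the gene subset (`"all"` when
#'   `genes` is NULL).
#' @param throughOrigin drop the intercept.
#' @return an [EpistasisResult-class].
#' @export
epistasisRegression <- function(additive, simultaneous, genes = NULL,
                                strain = NA_character_,
                                subsetLabel = if (is.null(genes)) "all"
                                              else "custom",
                                throughOrigin = FALSE) {
  x <- deltaValues(additive)
  y <- deltaValues(simultaneous)[names(x)]
  if (anyNA(y)) stop("delta profiles cover different gene sets")
  if (!is.null(genes)) {
    keep <- intersect(genes, names(x))
    x <- x[keep]
    y <- y[keep]
  }
  if (length(x) < 3L) stop("need at least 3 genes after subsetting")
  if (sd(x) == 0) stop("zero variance in the additive change")
  fit <- if (throughOrigin) lm(y ~ x + 0) else lm(y ~ x)
  co <- coef(fit)
  slope <- unname(co[["x"]])
  intercept <- if (throughOrigin) 0 else unname(co[[1L]])
  assoc <- tryCatch(
    list(r = unname(cor(x, y)),
         p = cor.test(x, y)$p.value),
    error = function(e) list(r = NA_real_, p = NA_real_))
  methods::new("EpistasisResult", strain = strain,
               nGenes = length(x), r = assoc$r, rPvalue = assoc$p,
               slope = slope, intercept = intercept,
               magnitude = 1 - slope, subset = subsetLabel)
}

#' Epistasis estimates for all evolved strains
#'
#' Runs [epistasisContrasts()] and [epistasisRegression()] per strain.
#' The correlation reported in each result is between `dHS_A` and `dG`
#' (the two contributors), while the regression relates simultaneous to
#' additive change.
#'
#' @param profiles a [ProfileSet-class].
#' @param strains evolved strain labels; default: every strain with an
#'   `_hs` profile except the ancestor.
#' @param ancestor ancestor label.
#' @param genes optional gene subset for the regression.
#' @param subsetLabel subset label recorded in the results.
#' @param throughOrigin drop the intercept.
#' @return list of [EpistasisResult-class], named by strain.
#' @export
epistasisTable <- function(profiles, strains = NULL, ancestor = "Anc",
                           genes = NULL,
                           subsetLabel = if (is.null(genes)) "all"
                                         else "custom",
                           throughOrigin = FALSE) {
  labs <- profileLabels(profiles)
  if (is.null(strains)) {
    hs <- sub("_hs$", "", grep("_hs$", labs, value = TRUE))
    strains <- setdiff(hs, ancestor)
  }
  out <- lapply(strains, function(s) {
    ct <- epistasisContrasts(profiles, s, ancestor)
    assoc <- deltaAssociation(ct$dHS_A, ct$dG)
    res <- epistasisRegression(ct$additive, ct$simultaneous,
                               genes = genes, strain = s,
                               subsetLabel = subsetLabel,
                               throughOrigin = throughOrigin)
    res@r <- assoc$r
    res@rPvalue <- assoc$p
    res
  })
  names(out) <- strains
  out
}

#' Alignment of heat-shock-induced and temperature-mediated change
#'
#' Pearson correlation between the ancestral heat-shock response
#' `dHS_A = Anc_hs - Anc_r` and a strain's growth-temperature-mediated
#' change `dT = strain_e - strain_r`. Increasing values along the
#' lineage indicate evolved steady states that echo the heat-shock
#' expression pattern.
#'
#' @param profiles a [ProfileSet-class].
#' @param strain strain label.
#' @param ancestor ancestor label.
#' @return Pearson correlation coefficient.
#' @export
responsivenessAlignment <- function(profiles, strain, ancestor = "Anc") {
  dHS <- makeDelta(profiles, paste0(ancestor, "_hs"),
                   paste0(ancestor, "_r"), name = "dHS_A")
  dT <- makeDelta(profiles, paste0(strain, "_e"), paste0(strain, "_r"),
                  name = paste0("dT_", strain))
  deltaAssociation(dHS, dT)$r
}
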