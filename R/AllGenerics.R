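#' @rdname globalNormalize
#' @export
setGeneric("globalNormalize", function(x, ...) standardGeneric("globalNormalize"))

#' @rdname runPCA
#' @export
setGeneric("runPCA", function(x, nComponents = NULL, center = TRUE, ...)
  standardGeneric("runPCA"))

#' Accessors
#'
#' Small accessor generics for the package's S4 classes: gene identifiers,
#' profile labels and the underlying numeric values.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("profileLabels", function(x) standardGeneric("profileLabels"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("deltaValues", function(x) standardGeneric("deltaValues"))

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname accessors
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname accessors
#' @export
setGeneric("experiment", function(x) standardGeneric("experiment"))
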