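## Generics. Accessors are generics in the Bioconductor idiom; methods are
## defined beside their classes / in the topical files.

#' @rdname GenotypeCounts
#' @param x,object an object.
#' @export
setGeneric("nAA", function(x) standardGeneric("nAA"))
#' @rdname GenotypeCounts
#' @export
setGeneric("nAa", function(x) standardGeneric("nAa"))
#' @rdname GenotypeCounts
#' @export
setGeneric("naa", function(x) standardGeneric("naa"))
#' @rdname GenotypeCounts
#' @export
setGeneric("popSize", function(x) standardGeneric("popSize"))

#' @rdname alleleFrequencies
#' @export
setGeneric("alleleFrequencies",
           function(x) standardGeneric("alleleFrequencies"))

#' @rdname hwExpectedCounts
#' @export
setGeneric("hwExpectedCounts",
           function(x) standardGeneric("hwExpectedCounts"))

#' @rdname hwChiSquare
#' @export
setGeneric("hwChiSquare", function(x) standardGeneric("hwChiSquare"))

#' @rdname subsampleCounts
#' @export
setGeneric("subsampleCounts", function(x, n) standardGeneric("subsampleCounts"))

#' @rdname ReproductionSpec
#' @param x a \code{ReproductionSpec}.
#' @export
setGeneric("meanOffspring", function(x) standardGeneric("meanOffspring"))

#' @rdname runTrajectory
#' @export
setGeneric("runTrajectory", function(config, ...) standardGeneric("runTrajectory"))

#' @rdname runChiSquareEnsemble
#' @export
setGeneric("runChiSquareEnsemble",
           function(config, ...) standardGeneric("runChiSquareEnsemble"))

#' @rdname EnsembleResult
#' @param x an \code{EnsembleResult}.
#' @export
setGeneric("chi2Values", function(x) standardGeneric("chi2Values"))

#' @rdname AcfResult
#' @export
setGeneric("acfValues", function(x) standardGeneric("acfValues"))
#' @rdname AcfResult
#' @export
setGeneric("noiseBand", function(x) standardGeneric("noiseBand"))
#' @rdname AcfResult
#' @export
setGeneric("crossingLag", function(x) standardGeneric("crossingLag"))
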