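#' @import methods
#' @importFrom stats dpois pnorm ppois qnorm rbinom rnorm rpois quantile sd
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' @export
setGeneric("logMean", function(x) standardGeneric("logMean"))

#' @export
setGeneric("logSd", function(x) standardGeneric("logSd"))

#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @export
setGeneric("functionalRatio", function(x) standardGeneric("functionalRatio"))

#' @export
setGeneric("phagoProb", function(x) standardGeneric("phagoProb"))

#' @export
setGeneric("fluorShift", function(x) standardGeneric("fluorShift"))

#' @export
setGeneric("q1", function(x) standardGeneric("q1"))

#' @export
setGeneric("q23", function(x) standardGeneric("q23"))

#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @export
setGeneric("alphaValues", function(x) standardGeneric("alphaValues"))

#' @export
setGeneric("mValues", function(x) standardGeneric("mValues"))

#' @export
setGeneric("nMax", function(x) standardGeneric("nMax"))

#' @export
setGeneric("uptakeThreshold", function(x) standardGeneric("uptakeThreshold"))

#' @export
setGeneric("markerThreshold", function(x) standardGeneric("markerThreshold"))

#' @export
setGeneric("uptakeFi", function(x) standardGeneric("uptakeFi"))

#' @export
setGeneric("markerFi", function(x) standardGeneric("markerFi"))

#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @export
setGeneric("corrections", function(x) standardGeneric("corrections"))
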