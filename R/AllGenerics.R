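## Generics (base statistical generics promoted to S4 plus package generics).

setGeneric("coef")
setGeneric("vcov")
setGeneric("logLik")
setGeneric("BIC")

#' @export
setGeneric("curveMean", function(object, x) standardGeneric("curveMean"))

#' @export
setGeneric("curveGradient",
           function(object, x) standardGeneric("curveGradient"))

#' @export
setGeneric("countPmf",
           function(object, k, log = FALSE) standardGeneric("countPmf"))

#' @export
setGeneric("countLogLik",
           function(object, freq) standardGeneric("countLogLik"))

#' @export
setGeneric("countSample", function(object, n) standardGeneric("countSample"))

#' @export
setGeneric("doses", function(object) standardGeneric("doses"))

#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))

#' @export
setGeneric("responseFamily",
           function(object) standardGeneric("responseFamily"))

#' @export
setGeneric("dispersionIndex",
           function(object) standardGeneric("dispersionIndex"))

#' @export
setGeneric("doseResponse", function(object) standardGeneric("doseResponse"))

#' @export
setGeneric("doseSummary",
           function(object, level = 0.95) standardGeneric("doseSummary"))
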