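#' Node symbols of a network or subnetwork
#' @param x an object with nodes.
#' @return character vector of node symbols.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Member symbols of a subnetwork
#' @param x a \linkS4class{Subnetwork}.
#' @return character vector of member symbols.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Calibrated score of a subnetwork
#' @param x a \linkS4class{Subnetwork}.
#' @return numeric calibrated score.
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' Total exonic length per gene of a chimeric model
#' @param x a \linkS4class{ChimericGeneModel}.
#' @return named integer vector of summed merged-exon widths.
#' @export
setGeneric("exonicLength", function(x) standardGeneric("exonicLength"))

#' Number of merged exons per gene of a chimeric model
#' @param x a \linkS4class{ChimericGeneModel}.
#' @return named integer vector.
#' @export
setGeneric("exonCount", function(x) standardGeneric("exonCount"))

#' Fitted variance of pooled counts at a given mean
#'
#' Evaluates the smooth mean-variance trend on the common (normalised) scale,
#' clamped from below at the Poisson variance.
#' @param object a \linkS4class{DispersionFit}.
#' @param mu numeric vector of means on the common scale.
#' @return numeric vector of fitted variances, always >= mu.
#' @export
setGeneric("fittedVariance",
           function(object, mu) standardGeneric("fittedVariance"))

#' Fitted negative binomial dispersion at a given mean
#'
#' The overdispersion alpha(mu) implied by the fitted trend after removing
#' the shot-noise component, floored at zero.
#' @param object a \linkS4class{DispersionFit}.
#' @param mu numeric vector of means on the common scale.
#' @return numeric vector of dispersions >= 0.
#' @export
setGeneric("fittedDispersion",
           function(object, mu) standardGeneric("fittedDispersion"))

#' Venn classes of a modulator partition
#' @param x a \linkS4class{ModulatorPartition}.
#' @return named list with elements onlyA, shared, onlyB.
#' @export
setGeneric("vennClasses", function(x) standardGeneric("vennClasses"))

setMethod("members", "Subnetwork", function(x) x@members)
setMethod("moduleScore", "Subnetwork", function(x) x@score)
setMethod("networkNodes", "Subnetwork", function(x) x@members)
setMethod("vennClasses", "ModulatorPartition", function(x)
  list(onlyA = x@onlyA, shared = x@shared, onlyB = x@onlyB))
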