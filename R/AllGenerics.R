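# Generics shared across classes.

#' Disease universe of an object
#' @param x a multiplex object.
#' @return character vector of disease identifiers.
#' @export
setGeneric("diseases", function(x) standardGeneric("diseases"))

#' Layer names
#' @param x a multiplex object.
#' @return character vector of layer names.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Number of layers
#' @param x a multiplex object.
#' @return integer.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Edge table of a layer
#' @param x a [DiseaseLayer-class].
#' @return \code{data.frame} with columns \code{from}, \code{to},
#'   \code{shared}.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Two-level map-equation codelength
#'
#' For a [FlowDistribution-class], computes the description length of the
#' given state-node partition; for a [MultiplexPartition-class], returns the
#' stored terms.
#'
#' @param object a flow distribution or partition.
#' @param ... method arguments; for flows, \code{assignment}.
#' @return a [MapEquationTerms-class].
#' @export
setGeneric("codelength", function(object, ...) standardGeneric("codelength"))

#' Community assignment of state nodes
#' @param x a [MultiplexPartition-class].
#' @return \code{data.frame} (\code{disease}, \code{layer},
#'   \code{community}, \code{visitRate}).
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))

#' Communities as disease sets
#'
#' The disease set of a community is the union of its member diseases over
#' layers (a disease appearing in a community through either layer counts
#' once).
#'
#' @param x a [MultiplexPartition-class].
#' @return named list of character vectors, one per community.
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' Recorded visit rates
#' @param x a flow distribution or partition.
#' @return named numeric vector over state nodes.
#' @export
setGeneric("visitRates", function(x) standardGeneric("visitRates"))
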