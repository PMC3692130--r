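#' @rdname PathwayGraph-class
#' @param object a \code{PathwayGraph}, \code{ActivationMatrix},
#'   \code{ReferenceModel} or \code{Circuit}.
#' @export
setGeneric("pathwayId", function(object) standardGeneric("pathwayId"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("pathwayNodes", function(object) standardGeneric("pathwayNodes"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("pathwayEdges", function(object) standardGeneric("pathwayEdges"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("receptors", function(object) standardGeneric("receptors"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("effectors", function(object) standardGeneric("effectors"))

#' @rdname ActivationMatrix-class
#' @param object an \code{ActivationMatrix}.
#' @export
setGeneric("activationValues",
           function(object) standardGeneric("activationValues"))

#' @rdname ActivationMatrix-class
#' @export
setGeneric("activationLevel",
           function(object) standardGeneric("activationLevel"))

#' @rdname ReferenceModel-class
#' @param object a \code{ReferenceModel}.
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname Circuit-class
#' @param object a \code{Circuit}.
#' @export
setGeneric("circuitId", function(object) standardGeneric("circuitId"))

#' @rdname Circuit-class
#' @export
setGeneric("circuitPaths", function(object) standardGeneric("circuitPaths"))

#' @rdname Circuit-class
#' @export
setGeneric("nodeUniverse", function(object) standardGeneric("nodeUniverse"))
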