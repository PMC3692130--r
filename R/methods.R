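#' @rdname PathwayGraph-class
#' @export
setMethod("pathwayId", "PathwayGraph", function(object) object@pathwayId)

#' @rdname PathwayGraph-class
#' @export
setMethod("pathwayNodes", "PathwayGraph", function(object) object@nodes)

#' @rdname PathwayGraph-class
#' @export
setMethod("pathwayEdges", "PathwayGraph", function(object) object@edges)

#' @rdname PathwayGraph-class
#' @export
setMethod("receptors", "PathwayGraph", function(object) object@receptors)

#' @rdname PathwayGraph-class
#' @export
setMethod("effectors", "PathwayGraph", function(object) object@effectors)

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph", sQuote(object@pathwayId),
      if (nzchar(object@pathwayName)) paste0("(", object@pathwayName, ")"),
      "\n")
  cat(" ", nrow(object@nodes), "nodes (",
      sum(object@nodes$kind == "complex"), "complexes ),",
      nrow(object@edges), "edges (",
      sum(object@edges$sign == -1L), "inhibitions )\n")
  cat("  receptors:", if (length(object@receptors))
    paste(object@receptors, collapse = ", ") else "<not identified>", "\n")
  cat("  effectors:", if (length(object@effectors))
    paste(object@effectors, collapse = ", ") else "<not identified>", "\n")
  invisible(NULL)
})

#' Construct an ActivationMatrix
#'
#' @param values numeric matrix of probabilities in \[0, 1\] with row and
#'   column (sample) names.
#' @param level what the rows represent: \code{"probe"}, \code{"gene"},
#'   \code{"node"} or \code{"circuit"}.
#' @return An \code{ActivationMatrix}.
#' @examples
#' m <- matrix(c(0.2, 0.9), 1, 2, dimnames = list("g1", c("s1", "s2")))
#' ActivationMatrix(m, "gene")
#' @export
ActivationMatrix <- function(values, level = "gene") {
  new("ActivationMatrix", values = values, level = level)
}

#' @rdname ActivationMatrix-class
#' @export
setMethod("activationValues", "ActivationMatrix",
          function(object) object@values)

#' @rdname ActivationMatrix-class
#' @export
setMethod("activationLevel", "ActivationMatrix",
          function(object) object@level)

#' @export
setMethod("dim", "ActivationMatrix", function(x) dim(x@values))

setMethod("show", "ActivationMatrix", function(object) {
  d <- dim(object@values)
  cat("ActivationMatrix:", d[1L], object@level, "rows x", d[2L],
      "samples; range [",
      sprintf("%.3g", min(object@values)), ",",
      sprintf("%.3g", max(object@values)), "]\n")
  invisible(NULL)
})

#' @rdname ReferenceModel-class
#' @export
setMethod("modelParams", "ReferenceModel", function(object) object@params)

setMethod("show", "ReferenceModel", function(object) {
  p <- object@params
  cat("ReferenceModel:", nrow(p), "probes;",
      sum(p$fitStatus == "ok"), "mixture fits,",
      sum(p$fitStatus == "fallback_ecdf"), "ecdf fallbacks\n")
  invisible(NULL)
})

#' @rdname Circuit-class
#' @export
setMethod("circuitId", "Circuit", function(object) object@circuitId)

#' @rdname Circuit-class
#' @export
setMethod("circuitPaths", "Circuit", function(object) object@paths)

#' @rdname Circuit-class
#' @export
setMethod("nodeUniverse", "Circuit", function(object)
  sort(unique(unlist(lapply(object@paths, `[[`, "nodes")))))

setMethod("show", "Circuit", function(object) {
  cat("Circuit", sQuote(object@circuitId), ":", length(object@paths),
      "path(s) over", length(nodeUniverse(object)), "nodes",
      if (object@truncated) "(path list truncated)", "\n")
  invisible(NULL)
})
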