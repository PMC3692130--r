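#' @import methods
NULL

#' PathwayGraph: a signed directed pathway topology
#'
#' Container for a signaling pathway parsed from a KGML document: nodes
#' (gene groups or protein complexes), signed edges (+1 activation, -1
#' inhibition), and the identified receptor (in-degree 0) and effector
#' (out-degree 0) nodes.
#'
#' @slot pathwayId single string, e.g. the KGML \code{name} attribute.
#' @slot pathwayName display title.
#' @slot nodes \code{data.frame} with columns \code{nodeId} (unique),
#'   \code{kind} (\code{"any_of"} for nodes of interchangeable proteins,
#'   \code{"complex"} for protein complexes), \code{label}, and a list
#'   column \code{members} of character vectors of gene identifiers.
#' @slot edges \code{data.frame} with columns \code{source}, \code{target},
#'   \code{sign} (integer, +1 or -1), \code{subtype} (original KGML
#'   relation subtype string).
#' @slot receptors,effectors character vectors of node ids; empty until
#'   \code{\link{identifyEndpoints}} is called.
#'
#' @seealso [parseKGML()], [identifyEndpoints()], [enumerateCircuits()]
#' @export
setClass("PathwayGraph",
         representation(pathwayId = "character",
                        pathwayName = "character",
                        nodes = "data.frame",
                        edges = "data.frame",
                        receptors = "character",
                        effectors = "character"))

setValidity("PathwayGraph", function(object) {
  msgs <- character(0)
  nd <- object@nodes
  ed <- object@edges
  need <- c("nodeId", "kind", "label", "members")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$nodeId))
    msgs <- c(msgs, "duplicated nodeId")
  if (!all(nd$kind %in% c("any_of", "complex")))
    msgs <- c(msgs, "kind must be 'any_of' or 'complex'")
  if (any(vapply(nd$members, length, 1L) < 1L))
    msgs <- c(msgs, "every node needs >= 1 member gene")
  if (any(vapply(nd$members, anyDuplicated, 1L) > 0L))
    msgs <- c(msgs, "duplicated gene id within a node's member list")
  if (nrow(ed)) {
    if (!all(c(ed$source, ed$target) %in% nd$nodeId)) {
      bad <- setdiff(c(ed$source, ed$target), nd$nodeId)
      msgs <- c(msgs, paste("edge endpoints not in nodes:",
                            paste(bad, collapse = ", ")))
    }
    if (!all(ed$sign %in% c(-1L, 1L)))
      msgs <- c(msgs, "edge signs must be +1 or -1")
    if (any(ed$source == ed$target))
      msgs <- c(msgs, "self-loop edges are not allowed")
  }
  if (!all(object@receptors %in% nd$nodeId) ||
      !all(object@effectors %in% nd$nodeId))
    msgs <- c(msgs, "receptors/effectors must be node ids")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ActivationMatrix: presence/activation probabilities per row and sample
#'
#' A probability matrix (all values in \[0, 1\]) whose rows are probes,
#' genes or pathway nodes and whose columns are samples.
#'
#' @slot values numeric matrix with unique row and column names.
#' @slot level one of \code{"probe"}, \code{"gene"}, \code{"node"},
#'   \code{"circuit"} — what the rows represent.
#'
#' @export
setClass("ActivationMatrix",
         representation(values = "matrix", level = "character"))

setValidity("ActivationMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have row and column names")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    return("duplicated row or sample ids")
  if (any(!is.finite(v))) return("non-finite probabilities")
  if (any(v < 0 | v > 1)) return("probabilities must lie in [0, 1]")
  if (length(object@level) != 1L ||
      !object@level %in% c("probe", "gene", "node", "circuit"))
    return("level must be one of probe/gene/node/circuit")
  TRUE
})

#' ReferenceModel: per-probe presence/absence mixture parameters
#'
#' Two-component normal mixture fitted per probe on a log2 reference
#' compendium; the component with the larger mean is labeled "present".
#' Probes whose fit degenerates fall back to the empirical distribution
#' of their reference values (\code{fitStatus == "fallback_ecdf"}).
#'
#' @slot params \code{data.frame} with one row per probe and columns
#'   \code{probeId}, \code{wAbsent}, \code{meanAbsent}, \code{sdAbsent},
#'   \code{wPresent}, \code{meanPresent}, \code{sdPresent},
#'   \code{fitStatus} (\code{"ok"} or \code{"fallback_ecdf"}).
#' @slot ecdfValues named list (probeId -> sorted numeric reference
#'   values), present only for fallback probes.
#'
#' @export
setClass("ReferenceModel",
         representation(params = "data.frame", ecdfValues = "list"))

setValidity("ReferenceModel", function(object) {
  p <- object@params
  need <- c("probeId", "wAbsent", "meanAbsent", "sdAbsent",
            "wPresent", "meanPresent", "sdPresent", "fitStatus")
  if (!all(need %in% names(p)))
    return(paste("params must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(p$probeId)) return("duplicated probeId")
  if (!all(p$fitStatus %in% c("ok", "fallback_ecdf")))
    return("fitStatus must be 'ok' or 'fallback_ecdf'")
  ok <- p$fitStatus == "ok"
  if (any(ok)) {
    w <- p$wAbsent[ok] + p$wPresent[ok]
    if (any(abs(w - 1) > 1e-6) || any(p$wAbsent[ok] < 0) ||
        any(p$wPresent[ok] < 0))
      return("component weights must be >= 0 and sum to 1")
    if (any(p$sdAbsent[ok] <= 0) || any(p$sdPresent[ok] <= 0))
      return("component sds must be > 0")
    if (any(p$meanPresent[ok] <= p$meanAbsent[ok]))
      return("meanPresent must exceed meanAbsent for fitStatus 'ok'")
  }
  fb <- p$probeId[p$fitStatus == "fallback_ecdf"]
  if (!all(fb %in% names(object@ecdfValues)))
    return("fallback probes must have stored reference values")
  TRUE
})

#' Circuit: one receptor-to-effector stimulus-response unit
#'
#' All simple directed paths from one receptor to one effector, with the
#' per-path role of each node: a node is inhibitor-role in a path when its
#' outgoing edge within that path is an inhibition (the node then lets
#' signal pass when deactivated); the effector is always activator-role.
#'
#' @slot circuitId string \code{"<pathway>:<receptor>-><effector>"}.
#' @slot receptor,effector node ids.
#' @slot paths list; each element is a list with \code{nodes} (character,
#'   receptor..effector) and \code{roles} (character, \code{"activator"} or
#'   \code{"inhibitor"}, parallel to \code{nodes}).
#' @slot truncated \code{TRUE} when path enumeration was cut at the
#'   per-circuit cap.
#'
#' @export
setClass("Circuit",
         representation(circuitId = "character",
                        receptor = "character",
                        effector = "character",
                        paths = "list",
                        truncated = "logical"))

setValidity("Circuit", function(object) {
  if (!length(object@paths)) return("a circuit needs >= 1 path")
  for (p in object@paths) {
    if (!all(c("nodes", "roles") %in% names(p)))
      return("each path needs 'nodes' and 'roles'")
    if (length(p$nodes) != length(p$roles))
      return("roles must parallel nodes")
    if (anyDuplicated(p$nodes)) return("paths must be simple")
    if (p$nodes[1L] != object@receptor ||
        p$nodes[length(p$nodes)] != object@effector)
      return("paths must run receptor -> effector")
    if (!all(p$roles %in% c("activator", "inhibitor")))
      return("roles must be 'activator' or 'inhibitor'")
    if (p$roles[length(p$roles)] != "activator")
      return("the effector is always activator-role")
  }
  TRUE
})
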