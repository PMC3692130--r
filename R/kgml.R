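#' Parse a KGML pathway document into a signed directed graph
#'
#' Reads a KEGG Markup Language (KGML) document and builds a
#' \linkS4class{PathwayGraph}. Entries of type \code{"gene"} become
#' \code{any_of} nodes (a KGML gene entry lists several gene ids when the
#' proteins are interchangeable); entries of type \code{"group"} become
#' \code{complex} nodes whose members are the union of their component
#' entries' genes. Entries of type \code{"map"} are dropped; entries of
#' type \code{"compound"} are dropped and relations passing through a
#' compound are contracted into a direct edge whose sign is the product of
#' the two hop signs (the model carries no compound-abundance
#' probabilities).
#'
#' Relation subtypes are binarized: \code{activation}, \code{expression},
#' \code{indirect effect}, \code{phosphorylation} and
#' \code{binding/association} give sign +1; \code{inhibition},
#' \code{repression}, \code{dephosphorylation} and \code{dissociation}
#' give sign -1; unknown subtypes default to +1 with a warning. When a
#' relation carries several subtypes, any inhibitory subtype makes the
#' edge an inhibition. Self-loops are dropped with a message.
#'
#' @param kgml path to a KGML file, or a single string of KGML XML.
#' @param geneIdNamespace prefix stripped from KGML gene identifiers
#'   (e.g. \code{"hsa"} turns \code{"hsa:7471"} into \code{"7471"});
#'   \code{NULL} strips any \code{"<org>:"} prefix.
#' @param identify if \code{TRUE} (default), receptor/effector nodes are
#'   identified with [identifyEndpoints()] before returning.
#' @return A validated \linkS4class{PathwayGraph}.
#' @examples
#' kgml <- makeToyKGML("diamond", seed = 1)
#' parseKGML(kgml)
#' @export
parseKGML <- function(kgml, geneIdNamespace = NULL, identify = TRUE) {
  doc <- tryCatch(
    if (length(kgml) == 1L && !grepl("<", kgml, fixed = TRUE))
      xml2::read_xml(kgml) else xml2::read_xml(paste(kgml, collapse = "\n")),
    error = function(e) stop("malformed KGML XML: ", conditionMessage(e),
                             call. = FALSE))
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing"))
    stop("not a KGML document: missing <pathway> root element")
  pid <- xml2::xml_attr(root, "name") %||% "pathway"
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- ""

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  if (!length(entries)) stop("empty pathway: no <entry> elements")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")
  elabel <- vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "graphics")
    lb <- if (inherits(g, "xml_missing")) NA_character_
          else xml2::xml_attr(g, "name")
    if (is.na(lb)) "" else sub(",.*$", "", lb)
  }, character(1))

  stripNs <- function(ids) {
    if (is.null(geneIdNamespace)) sub("^[A-Za-z0-9.]+:", "", ids)
    else sub(paste0("^", geneIdNamespace, ":"), "", ids)
  }
  geneIdx <- which(etype == "gene")
  grpIdx <- which(etype == "group")
  keep <- c(geneIdx, grpIdx)
  dropped <- setdiff(seq_along(entries), keep)  # map, compound, ortholog, ...

  members <- vector("list", length(entries))
  for (i in geneIdx)
    members[[i]] <- unique(stripNs(strsplit(ename[i], "[[:space:]]+")[[1]]))
  for (i in grpIdx) {
    comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "component"),
                           "id")
    gi <- match(comp, eid)
    if (anyNA(gi))
      stop("group entry ", eid[i], " references missing components: ",
           paste(comp[is.na(gi)], collapse = ", "))
    members[[i]] <- unique(unlist(members[gi]))
    if (!length(members[[i]]))
      stop("group entry ", eid[i], " has no gene members")
  }
  kind <- ifelse(seq_along(entries) %in% grpIdx &
                 vapply(members, length, 1L) >= 2L, "complex",
                 ifelse(seq_along(entries) %in% grpIdx, "any_of", "any_of"))
  # a 1-member group degenerates to any_of semantics (max == min)

  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  e1 <- xml2::xml_attr(rels, "entry1")
  e2 <- xml2::xml_attr(rels, "entry2")
  subtypeOf <- function(rel) {
    nm <- xml2::xml_attr(xml2::xml_find_all(rel, "subtype"), "name")
    nm[!is.na(nm)]
  }
  subnames <- lapply(rels, subtypeOf)
  missingIds <- setdiff(c(e1, e2), eid)
  if (length(missingIds))
    stop("relation references missing entry id(s): ",
         paste(unique(missingIds), collapse = ", "))

  negSubs <- c("inhibition", "repression", "dephosphorylation",
               "dissociation")
  posSubs <- c("activation", "expression", "indirect effect",
               "phosphorylation", "binding/association")
  relSign <- vapply(subnames, function(s) {
    if (!length(s)) {
      warning("relation without subtype treated as activation",
              call. = FALSE)
      return(1L)
    }
    unknown <- setdiff(s, c(negSubs, posSubs))
    if (length(unknown))
      warning("unknown relation subtype(s) ",
              paste(sQuote(unknown), collapse = ", "),
              " treated as activation", call. = FALSE)
    if (any(s %in% negSubs)) -1L else 1L
  }, integer(1))
  relLabel <- vapply(subnames, function(s)
    if (length(s)) paste(s, collapse = "+") else "unspecified", character(1))

  keepIds <- eid[keep]
  compoundIds <- eid[etype == "compound"]
  edges <- data.frame(source = e1, target = e2, sign = relSign,
                      subtype = relLabel, stringsAsFactors = FALSE)

  # contract relations running through a dropped compound entry
  if (length(compoundIds)) {
    thru <- edges$source %in% compoundIds | edges$target %in% compoundIds
    inc <- edges[thru & edges$target %in% compoundIds &
                   edges$source %in% keepIds, , drop = FALSE]
    out <- edges[thru & edges$source %in% compoundIds &
                   edges$target %in% keepIds, , drop = FALSE]
    contracted <- do.call(rbind, lapply(seq_len(nrow(inc)), function(i) {
      o <- out[out$source == inc$target[i], , drop = FALSE]
      if (!nrow(o)) return(NULL)
      data.frame(source = inc$source[i], target = o$target,
                 sign = inc$sign[i] * o$sign,
                 subtype = paste0("via_compound(", inc$subtype[i], "+",
                                  o$subtype, ")"),
                 stringsAsFactors = FALSE)
    }))
    nUncontracted <- sum(thru) - (if (is.null(contracted)) 0L else 0L)
    edges <- rbind(edges[!thru, , drop = FALSE], contracted)
    message(sum(thru), " compound-mediated relation hop(s) contracted/",
            "dropped in ", pid)
  }

  # drop relations touching other dropped entries (map links etc.)
  onKept <- edges$source %in% keepIds & edges$target %in% keepIds
  if (any(!onKept))
    message(sum(!onKept), " relation(s) touching dropped entries removed",
            " in ", pid)
  edges <- edges[onKept, , drop = FALSE]

  selfLoop <- edges$source == edges$target
  if (any(selfLoop)) {
    message(sum(selfLoop), " self-loop relation(s) dropped in ", pid)
    edges <- edges[!selfLoop, , drop = FALSE]
  }
  edges <- unique(edges)
  rownames(edges) <- NULL

  nodes <- data.frame(nodeId = eid[keep],
                      kind = kind[keep],
                      label = ifelse(nzchar(elabel[keep]), elabel[keep],
                                     eid[keep]),
                      stringsAsFactors = FALSE)
  nodes$members <- members[keep]
  if (!nrow(nodes)) stop("empty pathway: no gene or group entries retained")

  g <- new("PathwayGraph", pathwayId = pid, pathwayName = title,
           nodes = nodes, edges = edges,
           receptors = character(0), effectors = character(0))
  validObject(g)
  if (identify && nrow(edges)) g <- identifyEndpoints(g)
  g
}

#' Identify receptor and effector nodes of a pathway graph
#'
#' Receptors are the entry points of the signal and effectors its exits;
#' with no curated annotation available they are identified from topology:
#' receptors have in-degree 0 and out-degree >= 1, effectors out-degree 0
#' and in-degree >= 1. Isolated nodes (degree 0) belong to neither set and
#' are reported with a message. Curated endpoint lists can be supplied to
#' override the degree rule.
#'
#' @param graph a \linkS4class{PathwayGraph}.
#' @param receptors,effectors optional character vectors of curated node
#'   ids; when given they replace the degree rule for that side.
#' @return The graph with its \code{receptors}/\code{effectors} slots set.
#' @export
identifyEndpoints <- function(graph, receptors = NULL, effectors = NULL) {
  stopifnot(is(graph, "PathwayGraph"))
  ed <- graph@edges
  ids <- graph@nodes$nodeId
  outd <- table(factor(ed$source, levels = ids))
  ind <- table(factor(ed$target, levels = ids))
  isolated <- ids[outd == 0 & ind == 0]
  if (length(isolated))
    message(length(isolated), " isolated node(s) excluded from endpoints",
            " in ", graph@pathwayId, ": ",
            paste(utils::head(isolated, 5L), collapse = ", "),
            if (length(isolated) > 5L) ", ...")
  rec <- if (is.null(receptors)) ids[ind == 0 & outd >= 1] else {
    bad <- setdiff(receptors, ids)
    if (length(bad)) stop("curated receptors not in graph: ",
                          paste(bad, collapse = ", "))
    receptors
  }
  eff <- if (is.null(effectors)) ids[outd == 0 & ind >= 1] else {
    bad <- setdiff(effectors, ids)
    if (length(bad)) stop("curated effectors not in graph: ",
                          paste(bad, collapse = ", "))
    effectors
  }
  if (nrow(ed) && (!length(rec) || !length(eff)))
    stop("pathway ", graph@pathwayId, " has edges but no ",
         if (!length(rec)) "receptor" else "effector",
         " under the degree rule; the graph is probably a pure cycle -- ",
         "supply curated endpoint lists or break the cycle")
  graph@receptors <- sort(rec)
  graph@effectors <- sort(eff)
  validObject(graph)
  graph
}

#' Export a pathway graph as a Cytoscape SIF file
#'
#' One line per edge: \code{source<TAB>activates|inhibits<TAB>target}.
#'
#' @param graph a \linkS4class{PathwayGraph}.
#' @param file output path; \code{NULL} returns the lines invisibly
#'   without writing.
#' @return Invisibly, the SIF lines.
#' @export
exportSIF <- function(graph, file = NULL) {
  stopifnot(is(graph, "PathwayGraph"))
  ed <- graph@edges
  lines <- sprintf("%s\t%s\t%s", ed$source,
                   ifelse(ed$sign == 1L, "activates", "inhibits"),
                   ed$target)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
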