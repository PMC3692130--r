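# Stimulus-response circuits: all simple paths from one receptor to one
# effector, and the exact probability that at least one path transmits
# under node-wise independence.
#
# Per path, a node is "inhibitor-role" iff its outgoing edge within the
# path is an inhibition: an inhibitor lets signal pass when the protein is
# absent, so it contributes 1 - p to the transmission product. The
# effector is always activator-role (it must be present to execute the
# response). A path therefore transmits when all its activator-role nodes
# are present AND all its inhibitor-role nodes are absent.

# roles along one node sequence, from the signs of its edges
pathRoles <- function(nodeSeq, edgeSign) {
  m <- length(nodeSeq)
  roles <- rep("activator", m)
  if (m > 1L) {
    key <- paste(nodeSeq[-m], nodeSeq[-1L], sep = "\r")
    s <- edgeSign[key]
    if (anyNA(s)) stop("path uses a non-edge")
    roles[-m] <- ifelse(s == -1L, "inhibitor", "activator")
  }
  roles
}

edgeSignLookup <- function(graph) {
  ed <- graph@edges
  s <- ed$sign
  names(s) <- paste(ed$source, ed$target, sep = "\r")
  s
}

#' Enumerate receptor-to-effector circuits of a pathway
#'
#' For every (receptor, effector) pair connected by at least one simple
#' directed path of length at most \code{maxPathLength}, builds a
#' \linkS4class{Circuit} holding all such paths (deterministically ordered
#' lexicographically by node id sequence). Pairs whose path count exceeds
#' \code{maxPaths} are truncated to the first \code{maxPaths} paths with a
#' warning and a truncation flag. Cycles in the graph are harmless: simple
#' paths cannot traverse a node twice.
#'
#' @param graph a \linkS4class{PathwayGraph} with identified endpoints.
#' @param maxPaths per-circuit cap on the number of retained paths.
#' @param maxPathLength maximum path length in edges.
#' @return A named list of \linkS4class{Circuit} objects (possibly empty).
#' @examples
#' g <- parseKGML(makeToyKGML("diamond", seed = 1))
#' enumerateCircuits(g)
#' @export
enumerateCircuits <- function(graph, maxPaths = 1000L,
                              maxPathLength = 30L) {
  stopifnot(is(graph, "PathwayGraph"))
  if (!length(graph@receptors) || !length(graph@effectors))
    stop("graph has no identified endpoints; run identifyEndpoints() first")
  ed <- graph@edges
  if (!nrow(ed)) return(list())
  ig <- igraph::graph_from_data_frame(
    ed[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = graph@nodes$nodeId))
  signs <- edgeSignLookup(graph)
  circuits <- list()
  for (r in graph@receptors) {
    for (e in graph@effectors) {
      if (r == e) next
      sp <- igraph::all_simple_paths(ig, from = r, to = e, mode = "out",
                                     cutoff = maxPathLength)
      if (!length(sp)) next
      seqs <- lapply(sp, function(p) igraph::V(ig)$name[as.integer(p)])
      ord <- order(vapply(seqs, paste, character(1), collapse = "\r"),
                   method = "radix")
      seqs <- seqs[ord]
      truncated <- length(seqs) > maxPaths
      if (truncated) {
        warning("circuit ", r, "->", e, ": ", length(seqs),
                " paths truncated to ", maxPaths, call. = FALSE)
        seqs <- seqs[seq_len(maxPaths)]
      }
      paths <- lapply(seqs, function(s)
        list(nodes = s, roles = pathRoles(s, signs)))
      cid <- paste0(graph@pathwayId, ":", r, "->", e)
      circuits[[cid]] <- new("Circuit", circuitId = cid, receptor = r,
                             effector = e, paths = paths,
                             truncated = truncated)
    }
  }
  circuits
}

# one path as a requirement event: genes that must be ON / OFF
pathEvent <- function(path) {
  list(act = unique(path$nodes[path$roles == "activator"]),
       inact = unique(path$nodes[path$roles == "inhibitor"]))
}

eventProb <- function(ev, p) {
  prod(p[ev$act]) * prod(1 - p[ev$inact])
}

# intersection of two requirement events; NULL when contradictory
# (a node required both present and absent has probability zero).
# act/inact may be node names or integer indices into the probability
# vector; both stay disjoint unique sets.
eventIntersect <- function(a, b) {
  act <- unique(c(a$act, b$act))
  inact <- unique(c(a$inact, b$inact))
  if (length(act) + length(inact) >
      length(unique(c(act, inact)))) return(NULL)
  list(act = act, inact = inact)
}

# P(union of events) by recursive inclusion/exclusion:
# P(E1 u rest) = P(E1) + P(rest) - P({E1 n Ei})
unionProb <- function(events, p) {
  k <- length(events)
  if (k == 0L) return(0)
  if (k == 1L) return(eventProb(events[[1L]], p))
  e1 <- events[[1L]]
  rest <- events[-1L]
  inter <- lapply(rest, eventIntersect, a = e1)
  inter <- inter[!vapply(inter, is.null, logical(1))]
  eventProb(e1, p) + unionProb(rest, p) - unionProb(inter, p)
}

#' Transmission probability of a single path
#'
#' The product over the path's nodes of \code{p} for activator-role nodes
#' and \code{1 - p} for inhibitor-role nodes: every activator must be
#' present and every inhibitor absent for the signal to get through.
#'
#' @param path one element of [circuitPaths()]: a list with \code{nodes}
#'   and \code{roles}.
#' @param nodeProbs named numeric vector of node activation
#'   probabilities.
#' @return A probability.
#' @examples
#' pathTransmission(list(nodes = c("R", "A", "E"),
#'                       roles = rep("activator", 3)),
#'                  c(R = 0.9, A = 0.8, E = 0.7))  # 0.504
#' @export
pathTransmission <- function(path, nodeProbs) {
  miss <- setdiff(path$nodes, names(nodeProbs))
  if (length(miss))
    stop("missing node probabilities: ", paste(miss, collapse = ", "))
  eventProb(pathEvent(path), nodeProbs)
}

#' Exact circuit transmission probability by inclusion/exclusion
#'
#' The probability that at least one of the circuit's paths transmits,
#' assuming node states are independent within a sample. Computed exactly
#' by recursive inclusion/exclusion over path events, where the joint
#' probability of a set of paths all transmitting is the product of
#' \code{p} over nodes required present and \code{1 - p} over nodes
#' required absent, and zero when some node is required both (conflicting
#' roles across paths are allowed; such intersection terms vanish).
#'
#' @param circuit a \linkS4class{Circuit} with at most \code{pathCap}
#'   paths.
#' @param nodeProbs named numeric vector covering the circuit's node
#'   universe, values in \[0, 1\].
#' @param pathCap hard cap on the number of paths for exact
#'   inclusion/exclusion (worst case O(2^k)); beyond it, use
#'   [monteCarloTransmission()].
#' @return A probability.
#' @examples
#' g <- parseKGML(makeToyKGML("diamond", seed = 1))
#' cir <- enumerateCircuits(g)[[1]]
#' p <- c(0.9, 0.8, 0.7, 0.6)
#' names(p) <- nodeUniverse(cir)
#' circuitTransmission(cir, p)
#' @export
circuitTransmission <- function(circuit, nodeProbs, pathCap = 20L) {
  stopifnot(is(circuit, "Circuit"))
  if (length(circuit@paths) > pathCap)
    stop("circuit ", circuit@circuitId, " has ", length(circuit@paths),
         " paths (> cap ", pathCap, "); use monteCarloTransmission()")
  miss <- setdiff(nodeUniverse(circuit), names(nodeProbs))
  if (length(miss))
    stop("missing node probabilities: ", paste(miss, collapse = ", "))
  if (any(nodeProbs < 0 | nodeProbs > 1))
    stop("node probabilities must lie in [0, 1]")
  nodes <- nodeUniverse(circuit)
  pv <- unname(nodeProbs[nodes])
  events <- lapply(circuit@paths, function(path) {
    ev <- pathEvent(path)
    list(act = match(ev$act, nodes), inact = match(ev$inact, nodes))
  })
  clamp01(unionProb(events, pv))
}

# 0/1 state matrix for n nodes (n <= 16), one row per state
stateMatrix <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
}

#' Brute-force transmission probability by state enumeration
#'
#' Independent test oracle: enumerates all 2^n binary states of the
#' circuit's node universe, weighs each state by the product of node
#' Bernoulli probabilities, and sums over states in which at least one
#' path transmits (all its activator-role nodes present, all its
#' inhibitor-role nodes absent). Exact, and independent of the
#' inclusion/exclusion code path.
#'
#' @inheritParams circuitTransmission
#' @param nodeProbs named numeric vector of node probabilities, or a
#'   matrix (nodes x probability vectors, with node row names) to
#'   evaluate many probability vectors against one cached state
#'   enumeration.
#' @param maxNodes refuse above this node count (2^n states).
#' @return A probability (vector input) or a vector of probabilities,
#'   one per matrix column.
#' @export
bruteForceTransmission <- function(circuit, nodeProbs, maxNodes = 20L) {
  stopifnot(is(circuit, "Circuit"))
  nodes <- nodeUniverse(circuit)
  n <- length(nodes)
  if (n > maxNodes)
    stop("node universe of ", n, " exceeds the ", maxNodes,
         "-node enumeration limit")
  vec <- !is.matrix(nodeProbs)
  pm <- if (vec) matrix(nodeProbs, ncol = 1L,
                        dimnames = list(names(nodeProbs), NULL))
        else nodeProbs
  miss <- setdiff(nodes, rownames(pm))
  if (length(miss))
    stop("missing node probabilities: ", paste(miss, collapse = ", "))
  pm <- pm[nodes, , drop = FALSE]
  events <- lapply(circuit@paths, function(path) {
    ev <- pathEvent(path)
    list(act = match(ev$act, nodes), inact = match(ev$inact, nodes))
  })
  total <- numeric(ncol(pm))
  nHigh <- max(0L, n - 16L)
  nLow <- n - nHigh
  low <- stateMatrix(nLow)
  for (hi in seq_len(2^nHigh) - 1L) {
    hiBits <- if (nHigh) as.integer(intToBits(hi))[seq_len(nHigh)]
              else integer(0)
    states <- if (nHigh)
      cbind(low, matrix(hiBits, nrow(low), nHigh, byrow = TRUE))
    else low
    # which states transmit depends on topology only, not on p
    transmits <- rep(FALSE, nrow(states))
    for (ev in events) {
      ok <- rep(TRUE, nrow(states))
      if (length(ev$act))
        ok <- ok & rowSums(states[, ev$act, drop = FALSE]) ==
          length(ev$act)
      if (length(ev$inact))
        ok <- ok & rowSums(states[, ev$inact, drop = FALSE]) == 0L
      transmits <- transmits | ok
    }
    st <- states[transmits, , drop = FALSE]
    for (j in seq_len(ncol(pm))) {
      p <- pm[, j]
      # state probability: product over nodes of p^s (1-p)^(1-s)
      m <- st * rep(p, each = nrow(st)) +
        (1 - st) * rep(1 - p, each = nrow(st))
      total[j] <- total[j] + sum(exp(rowSums(log(m))))
    }
  }
  if (vec) total[1L] else total
}

#' Monte-Carlo transmission probability
#'
#' Seeded fallback for circuits whose path count exceeds the exact
#' inclusion/exclusion cap: samples independent node states and returns
#' the fraction of draws in which at least one path transmits.
#'
#' @inheritParams circuitTransmission
#' @param draws number of state draws.
#' @param seed RNG seed (local; the global RNG state is restored).
#' @return A probability estimate with attribute \code{stochastic = TRUE}.
#' @export
monteCarloTransmission <- function(circuit, nodeProbs, draws = 1e5,
                                   seed = 1L) {
  stopifnot(is(circuit, "Circuit"))
  nodes <- nodeUniverse(circuit)
  miss <- setdiff(nodes, names(nodeProbs))
  if (length(miss))
    stop("missing node probabilities: ", paste(miss, collapse = ", "))
  p <- nodeProbs[nodes]
  events <- lapply(circuit@paths, pathEvent)
  est <- withLocalSeed(seed, {
    states <- matrix(stats::runif(draws * length(nodes)) <
                       rep(p, each = draws), nrow = draws,
                     dimnames = list(NULL, nodes))
    transmits <- rep(FALSE, draws)
    for (ev in events) {
      ok <- rep(TRUE, draws)
      if (length(ev$act))
        ok <- ok & rowSums(states[, ev$act, drop = FALSE]) ==
          length(ev$act)
      if (length(ev$inact))
        ok <- ok & rowSums(states[, ev$inact, drop = FALSE]) == 0L
      transmits <- transmits | ok
    }
    mean(transmits)
  })
  attr(est, "stochastic") <- TRUE
  est
}

#' Per-sample transmission profiles for a set of circuits
#'
#' Applies [circuitTransmission()] to every circuit and sample of a
#' node-level activation matrix. Circuits beyond the exact path cap fall
#' back to seeded Monte-Carlo estimation and are flagged in the
#' \code{"stochastic"} attribute of the result.
#'
#' @param circuits list of \linkS4class{Circuit} objects.
#' @param nodeProbs \linkS4class{ActivationMatrix} at node level covering
#'   all circuit nodes.
#' @param pathCap exact inclusion/exclusion cap.
#' @param mcDraws,seed Monte-Carlo fallback parameters.
#' @return A numeric matrix (circuits x samples) of transmission
#'   probabilities with attribute \code{stochastic}, a named logical
#'   vector flagging Monte-Carlo circuits.
#' @export
profileCircuits <- function(circuits, nodeProbs, pathCap = 20L,
                            mcDraws = 1e5, seed = 1L) {
  stopifnot(is(nodeProbs, "ActivationMatrix"))
  v <- nodeProbs@values
  ids <- vapply(circuits, circuitId, character(1))
  out <- matrix(NA_real_, length(circuits), ncol(v),
                dimnames = list(ids, colnames(v)))
  stochastic <- logical(length(circuits))
  names(stochastic) <- ids
  for (i in seq_along(circuits)) {
    cir <- circuits[[i]]
    mc <- length(cir@paths) > pathCap
    stochastic[i] <- mc
    if (mc)
      message("circuit ", cir@circuitId, ": ", length(cir@paths),
              " paths > cap ", pathCap, "; Monte-Carlo fallback (",
              format(mcDraws, scientific = FALSE), " draws)")
    for (j in seq_len(ncol(v))) {
      p <- v[, j]
      out[i, j] <- if (mc)
        as.numeric(monteCarloTransmission(cir, p, draws = mcDraws,
                                          seed = seed + i * 1009L + j))
      else circuitTransmission(cir, p, pathCap = pathCap)
    }
  }
  attr(out, "stochastic") <- stochastic
  out
}
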