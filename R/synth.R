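# Synthetic fixtures: toy KGML pathways and generative case/control
# expression studies with planted differential circuits. The generator is
# the package's stand-in for a curated pathway plus a large reference
# compendium: per sample a gene's product is present or absent (a
# Bernoulli draw), and its probes' log2 intensities are drawn from the
# matching mixture component — which makes the activation module's
# posterior the Bayes-correct presence estimator and gives calibration
# tests a well-posed target.

kgmlEntry <- function(id, genes, label, org = "syn") {
  sprintf('  <entry id="%s" name="%s" type="gene">\n    <graphics name="%s" type="rectangle"/>\n  </entry>',
          id, paste0(org, ":", genes, collapse = " "), label)
}

kgmlGroup <- function(id, componentIds) {
  sprintf('  <entry id="%s" name="undefined" type="group">\n    <graphics name="%s" type="rectangle"/>\n%s\n  </entry>',
          id, paste0("grp", id),
          paste(sprintf('    <component id="%s"/>', componentIds),
                collapse = "\n"))
}

kgmlRelation <- function(e1, e2, sign) {
  sub <- if (sign == 1L) '<subtype name="activation" value="--&gt;"/>'
         else '<subtype name="inhibition" value="--|"/>'
  sprintf('  <relation entry1="%s" entry2="%s" type="PPrel">\n    %s\n  </relation>',
          e1, e2, sub)
}

kgmlDoc <- function(pid, title, entries, relations) {
  paste(c('<?xml version="1.0"?>',
          sprintf('<pathway name="path:%s" org="syn" number="1" title="%s">',
                  pid, title),
          entries, relations, "</pathway>"), collapse = "\n")
}

#' Generate a toy KGML pathway document
#'
#' Deterministic (seeded) generator of well-formed KGML text for testing
#' and simulation. Templates: \describe{
#'   \item{chain}{\code{k} nodes in a linear activation cascade.}
#'   \item{inhibitor_chain}{a chain whose second edge is an inhibition
#'     (exactly one inhibition edge).}
#'   \item{diamond}{receptor, two parallel branch nodes, effector;
#'     \code{nCopies} disjoint copies can be placed in one pathway to get
#'     several gene-disjoint circuits.}
#'   \item{random_dag}{\code{n} rank-ordered nodes; each forward pair is
#'     an edge with probability \code{density}, inhibitory with
#'     probability \code{inhibitionFraction}; acyclic by construction.}
#'   \item{complex_chain}{receptor -> complex (KGML group of two gene
#'     entries) -> effector; exercises group parsing.}
#' }
#' Each node carries one synthetic gene (\code{g<node>}) unless
#' \code{genesPerNode > 1}, which makes nodes of interchangeable
#' proteins.
#'
#' @param template one of \code{"chain"}, \code{"inhibitor_chain"},
#'   \code{"diamond"}, \code{"random_dag"}, \code{"complex_chain"}.
#' @param k chain length in nodes.
#' @param nCopies number of disjoint diamond components.
#' @param n,density,inhibitionFraction random DAG parameters.
#' @param genesPerNode genes per (non-group) node.
#' @param seed RNG seed (only \code{random_dag} draws random numbers, but
#'   the seed is part of the interface for all templates).
#' @param pathwayId id written into the document.
#' @return A single string of KGML XML, parseable by [parseKGML()].
#' @examples
#' cat(makeToyKGML("chain", k = 3, seed = 1))
#' @export
makeToyKGML <- function(template = c("chain", "inhibitor_chain", "diamond",
                                     "random_dag", "complex_chain"),
                        k = 4L, nCopies = 1L, n = 12L, density = 0.2,
                        inhibitionFraction = 0.2, genesPerNode = 1L,
                        seed = 1L, pathwayId = paste0("syn_", template)) {
  template <- match.arg(template)
  if (k < 2L || n < 2L || nCopies < 1L || genesPerNode < 1L)
    stop("inconsistent template parameters")
  if (inhibitionFraction < 0 || inhibitionFraction > 1)
    stop("inhibitionFraction must lie in [0, 1]")
  genesOf <- function(i) {
    if (genesPerNode == 1L) paste0("g", i)
    else paste0("g", i, letters[seq_len(genesPerNode)])
  }
  entries <- character(0)
  relations <- character(0)
  withLocalSeed(seed, {
    if (template %in% c("chain", "inhibitor_chain")) {
      for (i in seq_len(k))
        entries <- c(entries, kgmlEntry(i, genesOf(i), paste0("N", i)))
      inhibAt <- if (template == "inhibitor_chain") 2L else 0L
      for (i in seq_len(k - 1L))
        relations <- c(relations,
                       kgmlRelation(i, i + 1L,
                                    if (i == inhibAt) -1L else 1L))
    } else if (template == "diamond") {
      for (cp in seq_len(nCopies)) {
        base <- (cp - 1L) * 4L
        ids <- base + 1:4  # R, A, B, E
        for (i in ids)
          entries <- c(entries, kgmlEntry(i, genesOf(i), paste0("N", i)))
        relations <- c(relations,
                       kgmlRelation(ids[1L], ids[2L], 1L),
                       kgmlRelation(ids[1L], ids[3L], 1L),
                       kgmlRelation(ids[2L], ids[4L], 1L),
                       kgmlRelation(ids[3L], ids[4L], 1L))
      }
    } else if (template == "random_dag") {
      for (i in seq_len(n))
        entries <- c(entries, kgmlEntry(i, genesOf(i), paste0("N", i)))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (stats::runif(1) < density) {
          sgn <- if (stats::runif(1) < inhibitionFraction) -1L else 1L
          relations <- c(relations, kgmlRelation(i, j, sgn))
        }
      }
      if (!length(relations))
        relations <- kgmlRelation(1L, n, 1L)
    } else {  # complex_chain: R -> group(A, B) -> E
      entries <- c(kgmlEntry(1L, genesOf(1L), "R"),
                   kgmlEntry(2L, genesOf(2L), "A"),
                   kgmlEntry(3L, genesOf(3L), "B"),
                   kgmlGroup(4L, c(2L, 3L)),
                   kgmlEntry(5L, genesOf(5L), "E"))
      relations <- c(kgmlRelation(1L, 4L, 1L), kgmlRelation(4L, 5L, 1L))
    }
  })
  kgmlDoc(pathwayId, paste("synthetic", template, "pathway"),
          entries, relations)
}

#' Specification of a synthetic case/control study
#'
#' Bundles every knob of [simulateStudy()]. Defaults describe a small but
#' realistic microarray-style study: 15 cases vs 15 controls, 3 probes
#' per gene, a 500-array reference compendium, and per-probe mixture
#' components at log2 intensities 6 (absent) and 10 (present) with unit
#' sds — a 4-sd separation typical of expressed-vs-background Affymetrix
#' probe intensity modes.
#'
#' @param template,templateParams pathway topology passed to
#'   [makeToyKGML()].
#' @param nCase,nControl class sizes.
#' @param planted list of planted effects, each
#'   \code{list(circuit = <circuit id or index>, effect = <log-odds
#'   shift>)} applied to the presence probability of every gene on the
#'   circuit in the case class (negative = loss of signal).
#' @param mixture list with \code{meanAbsent}, \code{meanPresent},
#'   \code{sdAbsent}, \code{sdPresent}.
#' @param probesPerGene probes replicating each gene with independent
#'   component noise.
#' @param nReference reference compendium size (samples).
#' @param basePresenceRange baseline per-gene presence probabilities are
#'   drawn uniformly from this interval.
#' @param seed structural seed (topology, baseline presence draws).
#' @return A \code{SimulationSpec} list.
#' @export
simulationSpec <- function(template = "diamond",
                           templateParams = list(),
                           nCase = 15L, nControl = 15L,
                           planted = list(),
                           mixture = list(meanAbsent = 6,
                                          meanPresent = 10,
                                          sdAbsent = 1, sdPresent = 1),
                           probesPerGene = 3L,
                           nReference = 500L,
                           basePresenceRange = c(0.6, 0.95),
                           seed = 1L) {
  stopifnot(nCase >= 1L, nControl >= 1L, probesPerGene >= 1L,
            nReference >= 1L, length(basePresenceRange) == 2L)
  for (pl in planted)
    if (!is.finite(pl$effect)) stop("planted effect sizes must be finite")
  structure(list(template = template, templateParams = templateParams,
                 nCase = nCase, nControl = nControl, planted = planted,
                 mixture = mixture, probesPerGene = probesPerGene,
                 nReference = nReference,
                 basePresenceRange = basePresenceRange, seed = seed),
            class = "SimulationSpec")
}

# draw a probes x samples expression matrix given per-gene presence
# probabilities per sample column
drawExpression <- function(presenceProb, geneOf, probeIds, sampleIds,
                           mixture) {
  nGene <- nrow(presenceProb)
  nSamp <- ncol(presenceProb)
  state <- matrix(stats::runif(nGene * nSamp) < presenceProb,
                  nGene, nSamp, dimnames = dimnames(presenceProb))
  expr <- matrix(NA_real_, length(probeIds), nSamp,
                 dimnames = list(probeIds, sampleIds))
  for (i in seq_along(probeIds)) {
    st <- state[geneOf[i], ]
    expr[i, ] <- stats::rnorm(nSamp,
                              ifelse(st, mixture$meanPresent,
                                     mixture$meanAbsent),
                              ifelse(st, mixture$sdPresent,
                                     mixture$sdAbsent))
  }
  expr
}

# per-node generating probabilities from per-gene presence probabilities
nodeGeneratingProbs <- function(graph, genePresence) {
  nd <- graph@nodes
  vapply(seq_len(nrow(nd)), function(i) {
    p <- genePresence[nd$members[[i]]]
    if (nd$kind[i] == "complex") min(p) else max(p)
  }, numeric(1)) -> v
  names(v) <- nd$nodeId
  v
}

#' Simulate a complete synthetic case/control study
#'
#' Builds a toy pathway, draws baseline per-gene presence probabilities,
#' applies planted log-odds shifts to the case class, and generates a
#' reference compendium plus a study expression matrix: per sample each
#' gene's presence state is a Bernoulli draw at its class probability and
#' each of its probes draws a log2 value from the matching mixture
#' component. The ground-truth table carries each circuit's true
#' transmission probability per class, computed with
#' [bruteForceTransmission()] on the generating node probabilities.
#'
#' @param spec a [simulationSpec()].
#' @param sampleSeed seed for the sampling stage (reference and study
#'   draws); defaults to \code{spec$seed + 1}. Keeping \code{spec$seed}
#'   fixed while varying \code{sampleSeed} yields independent replicates
#'   of the same generator.
#' @param computeTruth compute the brute-force ground-truth table (skip
#'   for speed in large replicate loops).
#' @param drawReference draw the reference compendium (\code{FALSE}
#'   returns \code{reference = NULL}, for replicate loops that reuse one
#'   fitted model; the study draw then uses a different RNG stream
#'   position than with \code{TRUE}).
#' @return list with \code{kgml} (text), \code{graph}, \code{circuits},
#'   \code{reference} (probes x samples matrix), \code{expr} (study
#'   matrix), \code{design} (data.frame), \code{probeMap},
#'   \code{basePresence}, \code{casePresence}, \code{truth}
#'   (data.frame with \code{circuitId}, \code{trueControl},
#'   \code{trueCase}, \code{planted}).
#' @examples
#' study <- simulateStudy(simulationSpec(nCase = 4L, nControl = 4L,
#'                                       nReference = 50L, seed = 7))
#' study$truth
#' @export
simulateStudy <- function(spec, sampleSeed = spec$seed + 1L,
                          computeTruth = TRUE, drawReference = TRUE) {
  stopifnot(inherits(spec, "SimulationSpec"))
  kgml <- do.call(makeToyKGML,
                  c(list(template = spec$template, seed = spec$seed),
                    spec$templateParams))
  graph <- suppressMessages(parseKGML(kgml))
  circuits <- enumerateCircuits(graph)
  if (!length(circuits)) stop("template produced no circuits")
  genes <- sort(unique(unlist(graph@nodes$members)))

  basePresence <- withLocalSeed(spec$seed * 2L + 1L, {
    stats::setNames(stats::runif(length(genes),
                                 spec$basePresenceRange[1L],
                                 spec$basePresenceRange[2L]), genes)
  })

  casePresence <- basePresence
  plantedIds <- character(0)
  for (pl in spec$planted) {
    sel <- pl$circuit
    cid <- if (is.numeric(sel)) {
      if (sel < 1 || sel > length(circuits))
        stop("planted circuit index ", sel, " out of range")
      names(circuits)[sel]
    } else {
      hit <- names(circuits)[names(circuits) == sel |
                               grepl(sel, names(circuits), fixed = TRUE)]
      if (!length(hit))
        stop("planted circuit selector ", sQuote(sel),
             " matches no circuit")
      hit[1L]
    }
    plantedIds <- c(plantedIds, cid)
    nodes <- nodeUniverse(circuits[[cid]])
    gset <- unique(unlist(
      graph@nodes$members[match(nodes, graph@nodes$nodeId)]))
    casePresence[gset] <- stats::plogis(stats::qlogis(basePresence[gset]) +
                                          pl$effect)
  }

  probeMap <- data.frame(
    probeId = paste0(rep(genes, each = spec$probesPerGene), "_p",
                     seq_len(spec$probesPerGene)),
    geneId = rep(genes, each = spec$probesPerGene),
    stringsAsFactors = FALSE)
  geneOf <- probeMap$geneId

  refIds <- paste0("ref", seq_len(spec$nReference))
  ctlIds <- paste0("ctl", seq_len(spec$nControl))
  casIds <- paste0("case", seq_len(spec$nCase))
  out <- withLocalSeed(sampleSeed, {
    reference <- NULL
    if (drawReference) {
      refP <- matrix(basePresence, length(genes), spec$nReference,
                     dimnames = list(genes, refIds))
      reference <- drawExpression(refP, geneOf, probeMap$probeId, refIds,
                                  spec$mixture)
    }
    studyP <- cbind(
      matrix(basePresence, length(genes), spec$nControl,
             dimnames = list(genes, ctlIds)),
      matrix(casePresence, length(genes), spec$nCase,
             dimnames = list(genes, casIds)))
    expr <- drawExpression(studyP, geneOf, probeMap$probeId,
                           c(ctlIds, casIds), spec$mixture)
    list(reference = reference, expr = expr)
  })
  design <- data.frame(sampleId = c(ctlIds, casIds),
                       label = c(rep("control", spec$nControl),
                                 rep("case", spec$nCase)),
                       stringsAsFactors = FALSE)

  truth <- NULL
  if (computeTruth) {
    ctlNode <- nodeGeneratingProbs(graph, basePresence)
    casNode <- nodeGeneratingProbs(graph, casePresence)
    truth <- data.frame(
      circuitId = names(circuits),
      trueControl = vapply(circuits, bruteForceTransmission,
                           numeric(1), nodeProbs = ctlNode),
      trueCase = vapply(circuits, bruteForceTransmission,
                        numeric(1), nodeProbs = casNode),
      planted = names(circuits) %in% plantedIds,
      stringsAsFactors = FALSE, row.names = NULL)
  }

  list(kgml = kgml, graph = graph, circuits = circuits,
       reference = out$reference, expr = out$expr, design = design,
       probeMap = probeMap, basePresence = basePresence,
       casePresence = casePresence, truth = truth)
}
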