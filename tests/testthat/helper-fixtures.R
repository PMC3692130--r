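# shared fixture builders (all data generated in code, no files)

# build a Circuit directly from node sequences + graph edge signs
mkCircuit <- function(pathNodeSeqs, signs, id = "test:R->E") {
  sgn <- integer(0)
  for (nm in names(signs)) sgn[nm] <- signs[[nm]]
  paths <- lapply(pathNodeSeqs, function(s) {
    m <- length(s)
    roles <- rep("activator", m)
    if (m > 1L) {
      key <- paste(s[-m], s[-1L], sep = "\r")
      roles[-m] <- ifelse(sgn[key] == -1L, "inhibitor", "activator")
    }
    list(nodes = s, roles = roles)
  })
  first <- pathNodeSeqs[[1L]]
  new("Circuit", circuitId = id, receptor = first[1L],
      effector = first[length(first)], paths = paths, truncated = FALSE)
}

# edge sign helper: signs(c("R>A" = 1, "A>B" = -1)) keyed source\rtarget
edgeSigns <- function(...) {
  x <- c(...)
  out <- as.list(as.integer(x))
  names(out) <- gsub(">", "\r", names(x), fixed = TRUE)
  out
}

# a varied bank of fixture circuits: chains, diamonds, inhibitor
# variants and random DAGs, each paired with its node universe
circuitBank <- function(minCircuits = 50L, seed = 202L, maxNodes = 12L) {
  graphs <- list(
    parseKGML(makeToyKGML("chain", k = 3, seed = seed)),
    parseKGML(makeToyKGML("chain", k = 6, seed = seed)),
    parseKGML(makeToyKGML("inhibitor_chain", k = 4, seed = seed)),
    parseKGML(makeToyKGML("inhibitor_chain", k = 6, seed = seed)),
    parseKGML(makeToyKGML("diamond", seed = seed)),
    parseKGML(makeToyKGML("diamond", nCopies = 2, seed = seed)),
    parseKGML(makeToyKGML("complex_chain", seed = seed)))
  circuits <- unlist(lapply(graphs, enumerateCircuits))
  s <- seed
  while (length(circuits) < minCircuits) {
    s <- s + 1L
    g <- suppressMessages(parseKGML(
      makeToyKGML("random_dag", n = sample(6:maxNodes, 1L),
                  density = runif(1, 0.25, 0.5),
                  inhibitionFraction = runif(1, 0, 0.5), seed = s,
                  pathwayId = paste0("dag", s))))
    cc <- enumerateCircuits(g)
    cc <- cc[vapply(cc, function(x)
      length(nodeUniverse(x)) <= maxNodes &&
        length(circuitPaths(x)) <= 20L, logical(1))]
    circuits <- c(circuits, cc)
  }
  circuits
}

# seeded random probability matrix for a circuit's node universe
randProbMatrix <- function(circuit, nVectors, seed,
                           lo = 0.02, hi = 0.98) {
  nodes <- nodeUniverse(circuit)
  set.seed(seed)
  matrix(runif(length(nodes) * nVectors, lo, hi), length(nodes),
         nVectors, dimnames = list(nodes, NULL))
}

# exact two-sided rank-sum p-value by exhaustive label permutation
wilcoxPermOracle <- function(x, y) {
  all <- c(x, y)
  n <- length(all)
  idx <- utils::combn(n, length(x))
  wOf <- function(xi) {
    r <- rank(all)
    sum(r[xi]) - length(xi) * (length(xi) + 1) / 2
  }
  ws <- apply(idx, 2L, wOf)
  wObs <- wOf(seq_along(x))
  pLo <- mean(ws <= wObs)
  pHi <- mean(ws >= wObs)
  min(1, 2 * min(pLo, pHi))
}
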