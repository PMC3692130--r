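# circuit enumeration and transmission probabilities

test_that("enumeration yields the expected circuits and roles", {
  chain <- parseKGML(makeToyKGML("chain", k = 3, seed = 1))
  cc <- enumerateCircuits(chain)
  expect_length(cc, 1L)
  expect_length(circuitPaths(cc[[1]]), 1L)
  expect_equal(circuitPaths(cc[[1]])[[1]]$nodes, c("1", "2", "3"))
  expect_true(all(circuitPaths(cc[[1]])[[1]]$roles == "activator"))

  diamond <- parseKGML(makeToyKGML("diamond", seed = 1))
  cd <- enumerateCircuits(diamond)
  expect_length(cd, 1L)
  expect_length(circuitPaths(cd[[1]]), 2L)

  # R -> A -| B -> E: A's outgoing edge is the inhibition
  inh <- parseKGML(makeToyKGML("inhibitor_chain", k = 4, seed = 1))
  ci <- enumerateCircuits(inh)[[1]]
  roles <- circuitPaths(ci)[[1]]$roles
  expect_equal(roles, c("activator", "inhibitor", "activator",
                        "activator"))
})

test_that("path transmission is the product with 1-p at inhibitors", {
  allAct <- list(nodes = c("R", "A", "E"), roles = rep("activator", 3))
  expect_equal(pathTransmission(allAct, c(R = 1, A = 1, E = 1)), 1)
  expect_equal(pathTransmission(allAct, c(R = 0.9, A = 0.8, E = 0.7)),
               0.504)
  inh <- list(nodes = c("R", "A", "B", "E"),
              roles = c("activator", "inhibitor", "activator",
                        "activator"))
  p <- c(R = 0.9, A = 0.8, B = 0.3, E = 0.7)
  expect_equal(pathTransmission(inh, p), 0.9 * 0.2 * 0.3 * 0.7)
  # same value from the exhaustive 2^4 state oracle
  cir <- mkCircuit(list(c("R", "A", "B", "E")),
                   edgeSigns(c("R>A" = 1, "A>B" = -1, "B>E" = 1)))
  expect_equal(bruteForceTransmission(cir, p), 0.0378,
               tolerance = 1e-12)
  expect_error(pathTransmission(allAct, c(R = 0.9)), "missing node")
})

test_that("diamond inclusion/exclusion matches the closed form", {
  cir <- mkCircuit(list(c("R", "A", "E"), c("R", "B", "E")),
                   edgeSigns(c("R>A" = 1, "R>B" = 1, "A>E" = 1,
                               "B>E" = 1)))
  p <- c(R = 0.9, A = 0.8, B = 0.7, E = 0.6)
  expect_equal(circuitTransmission(cir, p),
               0.9 * (0.8 + 0.7 - 0.8 * 0.7) * 0.6, tolerance = 1e-15)
  expect_equal(bruteForceTransmission(cir, p), 0.50760,
               tolerance = 1e-12)
})

test_that("single-path circuits equal the path product", {
  set.seed(41)
  cir <- mkCircuit(list(c("R", "A", "B", "E")),
                   edgeSigns(c("R>A" = 1, "A>B" = -1, "B>E" = 1)))
  for (i in 1:100) {
    p <- setNames(runif(4), c("R", "A", "B", "E"))
    expect_equal(circuitTransmission(cir, p),
                 pathTransmission(circuitPaths(cir)[[1]], p),
                 tolerance = 1e-15)
    expect_equal(circuitTransmission(cir, p),
                 bruteForceTransmission(cir, p), tolerance = 1e-12)
  }
})

test_that("transmission respects boundary probabilities", {
  cir <- mkCircuit(list(c("R", "A", "E"), c("R", "B", "E")),
                   edgeSigns(c("R>A" = 1, "R>B" = 1, "A>E" = 1,
                               "B>E" = 1)))
  p0 <- setNames(rep(0, 4), c("R", "A", "B", "E"))
  p1 <- setNames(rep(1, 4), c("R", "A", "B", "E"))
  expect_equal(circuitTransmission(cir, p0), 0)
  expect_equal(circuitTransmission(cir, p1), 1)
  expect_equal(bruteForceTransmission(cir, p0), 0)
  expect_equal(bruteForceTransmission(cir, p1), 1)
  # vacuous union: no path event can transmit
  expect_equal(sigCircuits:::unionProb(list(), p0), 0)
})

test_that("conflicting roles across paths still match the oracle", {
  # A activates E on one path and inhibits F -> E on the other, so A is
  # activator-role and inhibitor-role in the same circuit
  cir <- mkCircuit(list(c("R", "A", "E"), c("R", "A", "F", "E")),
                   edgeSigns(c("R>A" = 1, "A>E" = 1, "A>F" = -1,
                               "F>E" = 1)))
  set.seed(42)
  for (i in 1:50) {
    p <- setNames(runif(4, 0.02, 0.98), c("R", "A", "E", "F"))
    expect_equal(circuitTransmission(cir, p),
                 bruteForceTransmission(cir, p), tolerance = 1e-12)
  }
})

test_that("inclusion/exclusion equals brute force across fixture bank", {
  set.seed(50)
  circuits <- circuitBank(minCircuits = 25L, seed = 300L)
  for (k in seq_along(circuits)) {
    cir <- circuits[[k]]
    pm <- randProbMatrix(cir, 40L, seed = 1000L + k)
    bf <- bruteForceTransmission(cir, pm)
    ie <- apply(pm, 2L, function(p) circuitTransmission(cir, p))
    expect_lt(max(abs(bf - ie)), 1e-12)
    expect_true(all(ie >= 0 & ie <= 1))
  }
})

test_that("transmission is monotone in consistently-signed nodes", {
  cir <- mkCircuit(list(c("R", "A", "B", "E"), c("R", "C", "E")),
                   edgeSigns(c("R>A" = 1, "A>B" = -1, "B>E" = 1,
                               "R>C" = 1, "C>E" = 1)))
  set.seed(51)
  eps <- 1e-4
  for (i in 1:100) {
    p <- setNames(runif(5, 0.05, 0.9), c("R", "A", "B", "C", "E"))
    base <- circuitTransmission(cir, p)
    for (nd in c("R", "B", "C", "E")) {   # always activator-role
      up <- p; up[nd] <- up[nd] + eps
      expect_gte(circuitTransmission(cir, up), base - 1e-12)
    }
    dn <- p; dn["A"] <- dn["A"] + eps     # always inhibitor-role
    expect_lte(circuitTransmission(cir, dn), base + 1e-12)
  }
})

test_that("adding a path never decreases the union probability", {
  set.seed(52)
  signs <- edgeSigns(c("R>A" = 1, "A>E" = 1, "R>B" = -1, "B>E" = 1,
                       "R>C" = 1, "C>E" = -1))
  one <- mkCircuit(list(c("R", "A", "E")), signs)
  two <- mkCircuit(list(c("R", "A", "E"), c("R", "B", "E")), signs)
  three <- mkCircuit(list(c("R", "A", "E"), c("R", "B", "E"),
                          c("R", "C", "E")), signs)
  for (i in 1:100) {
    p <- setNames(runif(5), c("R", "A", "B", "C", "E"))
    t1 <- circuitTransmission(one, p)
    t2 <- circuitTransmission(two, p)
    t3 <- circuitTransmission(three, p)
    expect_gte(t2, t1 - 1e-12)
    expect_gte(t3, t2 - 1e-12)
  }
})

test_that("closed forms hold for chains with and without inhibitors", {
  set.seed(53)
  kchain <- parseKGML(makeToyKGML("chain", k = 5, seed = 1))
  cc <- enumerateCircuits(kchain)[[1]]
  inh <- parseKGML(makeToyKGML("inhibitor_chain", k = 5, seed = 1))
  ci <- enumerateCircuits(inh)[[1]]
  for (i in 1:50) {
    p <- setNames(runif(5), as.character(1:5))
    expect_equal(circuitTransmission(cc, p), prod(p),
                 tolerance = 1e-15)
    # node "2" carries the inhibition edge
    expect_equal(circuitTransmission(ci, p),
                 as.numeric(prod(p[-2]) * (1 - p[2])),
                 tolerance = 1e-15)
  }
})

test_that("Monte-Carlo fallback approximates the exact value", {
  cir <- mkCircuit(list(c("R", "A", "E"), c("R", "B", "E")),
                   edgeSigns(c("R>A" = 1, "R>B" = 1, "A>E" = 1,
                               "B>E" = 1)))
  p <- c(R = 0.9, A = 0.8, B = 0.7, E = 0.6)
  est1 <- monteCarloTransmission(cir, p, draws = 2e5, seed = 7)
  est2 <- monteCarloTransmission(cir, p, draws = 2e5, seed = 7)
  expect_identical(as.numeric(est1), as.numeric(est2))  # seeded
  expect_true(attr(est1, "stochastic"))
  expect_lt(abs(as.numeric(est1) - circuitTransmission(cir, p)), 0.005)
})

test_that("profiling a matrix equals per-sample transmission calls", {
  g <- parseKGML(makeToyKGML("diamond", seed = 1))
  cc <- enumerateCircuits(g)
  set.seed(54)
  nodeM <- matrix(runif(12), 4, 3,
                  dimnames = list(pathwayNodes(g)$nodeId,
                                  paste0("s", 1:3)))
  prof <- profileCircuits(cc, ActivationMatrix(nodeM, "node"))
  expect_equal(dim(prof), c(1L, 3L))
  for (j in 1:3)
    expect_equal(prof[1, j], circuitTransmission(cc[[1]], nodeM[, j]))
  # identical samples give identical probabilities
  nodeM2 <- nodeM[, c(1, 1)]
  colnames(nodeM2) <- c("a", "b")
  prof2 <- profileCircuits(cc, ActivationMatrix(nodeM2, "node"))
  expect_equal(prof2[1, "a"], prof2[1, "b"])
  # all-ones sample on an activator-only circuit transmits surely
  ones <- matrix(1, 4, 1, dimnames = list(rownames(nodeM), "s"))
  expect_equal(profileCircuits(cc, ActivationMatrix(ones, "node"))[1, 1],
               1)
})

test_that("path caps trigger truncation and the Monte-Carlo route", {
  g <- parseKGML(makeToyKGML("diamond", seed = 1))
  expect_warning(cc <- enumerateCircuits(g, maxPaths = 1L),
                 "truncated")
  expect_true(cc[[1]]@truncated)
  expect_length(circuitPaths(cc[[1]]), 1L)

  full <- enumerateCircuits(g)
  p <- setNames(rep(0.5, 4), pathwayNodes(g)$nodeId)
  expect_error(circuitTransmission(full[[1]], p, pathCap = 1L),
               "monteCarloTransmission")
  nodeM <- matrix(0.5, 4, 1, dimnames = list(pathwayNodes(g)$nodeId,
                                             "s1"))
  prof <- suppressMessages(
    profileCircuits(full, ActivationMatrix(nodeM, "node"),
                    pathCap = 1L, mcDraws = 2e5))
  expect_true(attr(prof, "stochastic")[1])
  expect_lt(abs(prof[1, 1] - circuitTransmission(full[[1]], p)), 0.005)
})
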