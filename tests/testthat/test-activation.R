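# expression -> presence probability conversion

mkRef <- function(x, probe = "p1") {
  matrix(x, nrow = 1, dimnames = list(probe, NULL))
}

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(11)
  x <- c(rnorm(250, 6, 1), rnorm(250, 10, 1))
  m <- fitReferenceModel(mkRef(x))
  p <- modelParams(m)
  expect_equal(p$fitStatus, "ok")
  expect_lt(abs(p$meanAbsent - 6), 0.15)
  expect_lt(abs(p$meanPresent - 10), 0.15)
  expect_lt(abs(p$wPresent - 0.5), 0.06)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  set.seed(12)
  x <- c(rnorm(300, 5, 0.8), rnorm(200, 9, 1.2))
  p <- modelParams(fitReferenceModel(mkRef(x)))
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  means <- sort(mc$parameters$mean)
  expect_lt(abs(p$meanAbsent - means[1]), 0.1)
  expect_lt(abs(p$meanPresent - means[2]), 0.1)
})

test_that("degenerate references fall back to the empirical distribution", {
  # constant probe: zero variance
  m1 <- suppressMessages(fitReferenceModel(mkRef(rep(7, 50))))
  expect_equal(modelParams(m1)$fitStatus, "fallback_ecdf")
  # single well-behaved component: weight floor triggers
  set.seed(13)
  m2 <- suppressMessages(fitReferenceModel(mkRef(rnorm(500, 8, 1))))
  expect_equal(modelParams(m2)$fitStatus, "fallback_ecdf")
  # sample floor
  set.seed(14)
  expect_error(fitReferenceModel(mkRef(rnorm(10))), "floor")
})

test_that("posterior activation follows the mixture", {
  params <- data.frame(probeId = "p1", wAbsent = 0.5, meanAbsent = 6,
                       sdAbsent = 1, wPresent = 0.5, meanPresent = 10,
                       sdPresent = 1, fitStatus = "ok",
                       stringsAsFactors = FALSE)
  model <- new("ReferenceModel", params = params, ecdfValues = list())
  ex <- matrix(c(8, 6, 10, 30, -20), 1,
               dimnames = list("p1", paste0("s", 1:5)))
  a <- activationValues(probeActivation(ex, model))
  expect_equal(a[1, "s1"], 0.5)            # symmetric midpoint
  expect_gt(a[1, "s3"], 0.97)
  expect_lt(a[1, "s2"], 0.03)
  expect_equal(a[1, "s4"], 1)              # far-right limit
  expect_equal(a[1, "s5"], 0)              # far-left limit
  # nondecreasing in the expression value
  grid <- matrix(seq(2, 14, by = 0.1), 1,
                 dimnames = list("p1", paste0("g", seq(2, 14, by = 0.1))))
  post <- activationValues(probeActivation(grid, model))[1, ]
  expect_true(all(diff(post) >= 0))
})

test_that("fallback probes use the mid-rank empirical fraction", {
  ref <- mkRef(rep(7, 20))
  model <- suppressMessages(fitReferenceModel(ref))
  # hand-built distinct reference for the mid-rank formula
  refv <- sort(1:10)
  model@ecdfValues[["p1"]] <- as.numeric(refv)
  ex <- matrix(c(10, 0.5, 5.5, 20), 1,
               dimnames = list("p1", paste0("s", 1:4)))
  a <- activationValues(probeActivation(ex, model))
  expect_equal(a[1, "s1"], (10 - 0.5) / 10)  # value == reference max
  expect_equal(a[1, "s2"], 0)
  expect_equal(a[1, "s3"], 0.5)
  expect_equal(a[1, "s4"], 1)
  expect_error(probeActivation(
    matrix(1, 1, 1, dimnames = list("missing", "s")), model),
    "missing from the reference model")
})

test_that("probe-to-gene summarization implements the stated methods", {
  m <- matrix(c(0.2, 0.5, 0.9), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  am <- ActivationMatrix(m, "probe")
  map <- data.frame(probeId = c("a", "b", "c"), geneId = "g1")
  getv <- function(method)
    activationValues(geneActivation(am, map, method = method))[1, 1]
  # h = 0.9 * (3 - 1) = 1.8 -> 0.5 + 0.8 * (0.9 - 0.5)
  expect_equal(getv("percentile90"), 0.82)
  expect_equal(getv("max"), 0.9)
  expect_equal(getv("mean"), mean(c(0.2, 0.5, 0.9)))
  expect_equal(getv("median"), 0.5)
  # single probe: identical under every method
  one <- ActivationMatrix(matrix(0.7, 1, 1,
                                 dimnames = list("a", "s1")), "probe")
  map1 <- data.frame(probeId = "a", geneId = "g1")
  for (meth in c("percentile90", "mean", "median", "max"))
    expect_equal(activationValues(
      geneActivation(one, map1, method = meth))[1, 1], 0.7)
})

test_that("summary methods respect the order-statistic ordering", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    m <- matrix(runif(n * 3), n, 3,
                dimnames = list(paste0("p", 1:n), paste0("s", 1:3)))
    am <- ActivationMatrix(m, "probe")
    map <- data.frame(probeId = paste0("p", 1:n), geneId = "g")
    q90 <- activationValues(geneActivation(am, map, "percentile90"))
    mx <- activationValues(geneActivation(am, map, "max"))
    md <- activationValues(geneActivation(am, map, "median"))
    expect_true(all(mx >= q90 - 1e-12))
    expect_true(all(q90 >= md - 1e-12))
  }
})

test_that("node summarization: max for alternatives, min for complexes", {
  nodes <- data.frame(nodeId = c("n1", "n2", "n3"),
                      kind = c("any_of", "complex", "any_of"),
                      label = c("n1", "n2", "n3"),
                      stringsAsFactors = FALSE)
  nodes$members <- list(c("gA", "gB"), c("gA", "gB"), "gC")
  g <- new("PathwayGraph", pathwayId = "p", pathwayName = "",
           nodes = nodes,
           edges = data.frame(source = character(0),
                              target = character(0),
                              sign = integer(0),
                              subtype = character(0)),
           receptors = character(0), effectors = character(0))
  gm <- matrix(c(0.3, 0.8, 0.42), 3, 1,
               dimnames = list(c("gA", "gB", "gC"), "s1"))
  nv <- activationValues(nodeActivation(ActivationMatrix(gm, "gene"), g))
  expect_equal(nv["n1", 1], 0.8)   # alternative proteins: highest
  expect_equal(nv["n2", 1], 0.3)   # complex: lowest
  expect_equal(nv["n3", 1], 0.42)  # single member: identity

  # partial coverage warns; empty coverage errors
  gm2 <- gm[c("gA", "gC"), , drop = FALSE]
  w <- capture_warnings(
    nv2 <- nodeActivation(ActivationMatrix(gm2, "gene"), g))
  expect_match(w, "missing", all = TRUE)
  expect_length(w, 2L)  # n1 and n2 each miss gB
  expect_equal(activationValues(nv2)["n2", 1], 0.3)  # min over observed
  expect_error(nodeActivation(ActivationMatrix(gm2, "gene"), g,
                              missingMembers = "error"), "missing")
  gm3 <- gm["gC", , drop = FALSE]
  expect_error(suppressWarnings(
    nodeActivation(ActivationMatrix(gm3, "gene"), g)),
    "no member gene")
})

test_that("activation probabilities always lie in [0, 1]", {
  set.seed(31)
  x <- c(rnorm(300, 5), rnorm(300, 11))
  model <- fitReferenceModel(mkRef(x))
  ex <- matrix(seq(-50, 60, length.out = 40), 1,
               dimnames = list("p1", paste0("s", 1:40)))
  a <- activationValues(probeActivation(ex, model))
  expect_true(all(a >= 0 & a <= 1))
})
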