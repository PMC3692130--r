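# KGML parsing into signed directed pathway graphs

simpleKGML <- function(entries, relations) {
  paste(c('<?xml version="1.0"?>',
          '<pathway name="path:test01" org="tst" title="test">',
          entries, relations, "</pathway>"), collapse = "\n")
}

geneEntry <- function(id, genes) {
  sprintf('<entry id="%d" name="%s" type="gene"><graphics name="G%d"/></entry>',
          id, paste0("tst:", genes, collapse = " "), id)
}

rel <- function(e1, e2, subtype) {
  sprintf('<relation entry1="%d" entry2="%d" type="PPrel"><subtype name="%s" value="x"/></relation>',
          e1, e2, subtype)
}

test_that("gene entries and signed relations parse to nodes and edges", {
  k <- simpleKGML(c(geneEntry(1, "10"), geneEntry(2, "20"),
                    geneEntry(3, "30")),
                  c(rel(1, 2, "activation"), rel(2, 3, "inhibition")))
  g <- parseKGML(k)
  expect_s4_class(g, "PathwayGraph")
  expect_equal(nrow(pathwayNodes(g)), 3L)
  expect_equal(nrow(pathwayEdges(g)), 2L)
  expect_equal(pathwayEdges(g)$sign, c(1L, -1L))
  expect_true(all(pathwayNodes(g)$kind == "any_of"))
  # namespace prefix stripped from member gene ids
  expect_equal(pathwayNodes(g)$members[[1]], "10")
})

test_that("the relation subtype table binarizes signs as documented", {
  pos <- c("activation", "expression", "indirect effect",
           "phosphorylation", "binding/association")
  neg <- c("inhibition", "repression", "dephosphorylation",
           "dissociation")
  for (s in pos) {
    g <- parseKGML(simpleKGML(c(geneEntry(1, "1"), geneEntry(2, "2")),
                              rel(1, 2, s)))
    expect_equal(pathwayEdges(g)$sign, 1L, info = s)
  }
  for (s in neg) {
    g <- parseKGML(simpleKGML(c(geneEntry(1, "1"), geneEntry(2, "2")),
                              rel(1, 2, s)))
    expect_equal(pathwayEdges(g)$sign, -1L, info = s)
  }
  expect_warning(
    g <- parseKGML(simpleKGML(c(geneEntry(1, "1"), geneEntry(2, "2")),
                              rel(1, 2, "made-up-subtype"))),
    "unknown relation subtype")
  expect_equal(pathwayEdges(g)$sign, 1L)
})

test_that("group entries become complex nodes with member unions", {
  k <- simpleKGML(
    c(geneEntry(1, c("10", "11")), geneEntry(2, "20"),
      '<entry id="3" name="undefined" type="group"><component id="1"/><component id="2"/></entry>',
      geneEntry(4, "40")),
    rel(4, 3, "activation"))
  g <- parseKGML(k, identify = FALSE)
  nd <- pathwayNodes(g)
  expect_equal(nrow(nd), 4L)
  grp <- nd[nd$nodeId == "3", ]
  expect_equal(grp$kind, "complex")
  expect_setequal(grp$members[[1]], c("10", "11", "20"))
  # multi-gene KGML gene entry = interchangeable proteins
  expect_equal(nd$kind[nd$nodeId == "1"], "any_of")
  expect_setequal(nd$members[nd$nodeId == "1"][[1]], c("10", "11"))
})

test_that("map entries are dropped and compound relations contracted", {
  k <- simpleKGML(
    c(geneEntry(1, "10"),
      '<entry id="2" name="cpd:C00001" type="compound"><graphics name="C1"/></entry>',
      geneEntry(3, "30"),
      '<entry id="4" name="path:other" type="map"><graphics name="M"/></entry>'),
    c(rel(1, 2, "activation"), rel(2, 3, "inhibition"),
      rel(3, 4, "activation")))
  g <- suppressMessages(parseKGML(k))
  nd <- pathwayNodes(g)
  expect_setequal(nd$nodeId, c("1", "3"))
  ed <- pathwayEdges(g)
  # 1 -> (compound) -> 3 contracted; sign = (+1) * (-1)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$source, "1")
  expect_equal(ed$target, "3")
  expect_equal(ed$sign, -1L)
})

test_that("self-loops are dropped and bad references are errors", {
  k <- simpleKGML(c(geneEntry(1, "10"), geneEntry(2, "20")),
                  c(rel(1, 1, "activation"), rel(1, 2, "activation")))
  g <- suppressMessages(parseKGML(k))
  expect_equal(nrow(pathwayEdges(g)), 1L)

  expect_error(parseKGML(simpleKGML(geneEntry(1, "10"),
                                    rel(1, 9, "activation"))),
               "missing entry")
  expect_error(parseKGML("<pathway><entry"), "malformed")
  expect_error(parseKGML(simpleKGML(
    '<entry id="1" name="path:x" type="map"/>', character(0))),
    "empty pathway")
})

test_that("endpoint identification follows the degree rule", {
  chain <- parseKGML(makeToyKGML("chain", k = 3, seed = 1))
  expect_equal(receptors(chain), "1")
  expect_equal(effectors(chain), "3")

  diamond <- parseKGML(makeToyKGML("diamond", seed = 1))
  expect_equal(receptors(diamond), "1")
  expect_equal(effectors(diamond), "4")

  two <- parseKGML(simpleKGML(
    c(geneEntry(1, "1"), geneEntry(2, "2"), geneEntry(3, "3"),
      geneEntry(4, "4")),
    c(rel(1, 2, "activation"), rel(3, 4, "activation"))))
  expect_setequal(receptors(two), c("1", "3"))
  expect_setequal(effectors(two), c("2", "4"))

  # idempotent, topology-only
  expect_equal(identifyEndpoints(chain), chain)
})

test_that("isolated nodes are excluded and pure cycles are diagnosed", {
  k <- simpleKGML(c(geneEntry(1, "1"), geneEntry(2, "2"),
                    geneEntry(3, "3")),
                  rel(1, 2, "activation"))
  expect_message(g <- parseKGML(k), "isolated")
  expect_false("3" %in% c(receptors(g), effectors(g)))

  cyc <- simpleKGML(c(geneEntry(1, "1"), geneEntry(2, "2")),
                    c(rel(1, 2, "activation"), rel(2, 1, "activation")))
  expect_error(parseKGML(cyc), "pure cycle")
  # curated endpoints rescue a cyclic graph
  g2 <- identifyEndpoints(parseKGML(cyc, identify = FALSE),
                          receptors = "1", effectors = "2")
  expect_equal(receptors(g2), "1")
})

test_that("generated KGML round-trips: same seed, identical graph", {
  k1 <- makeToyKGML("random_dag", n = 15, density = 0.2, seed = 42)
  k2 <- makeToyKGML("random_dag", n = 15, density = 0.2, seed = 42)
  expect_identical(k1, k2)
  g1 <- suppressMessages(parseKGML(k1))
  g2 <- suppressMessages(parseKGML(k2))
  expect_equal(pathwayNodes(g1), pathwayNodes(g2))
  expect_equal(pathwayEdges(g1), pathwayEdges(g2))
  expect_true(all(pathwayEdges(g1)$sign %in% c(-1L, 1L)))
})

test_that("SIF export writes one signed interaction per edge", {
  g <- parseKGML(makeToyKGML("inhibitor_chain", k = 4, seed = 1))
  lines <- exportSIF(g)
  expect_length(lines, 3L)
  expect_equal(sum(grepl("\tinhibits\t", lines)), 1L)
  expect_equal(sum(grepl("\tactivates\t", lines)), 2L)
})
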