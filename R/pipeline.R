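# Orchestration: strict TSV readers/writers for every schema the tool
# exchanges, and runPipeline(), which drives raw inputs to result tables,
# Cytoscape exports and a JSON run manifest. read.delim/write TSV handle
# `.gz` transparently through R connections.

#' Read an expression (or reference) matrix from TSV
#'
#' Header row of sample ids, first column of probe/gene row ids.
#'
#' @param file path (plain or \code{.gz}).
#' @return numeric matrix with row and column names.
#' @export
readExpressionMatrix <- function(file) {
  d <- utils::read.delim(file, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expression file needs an id column plus >= 1 ",
                         "sample column")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    line <- which(duplicated(ids))[1L] + 1L  # +1 for the header row
    stop("duplicated row id ", sQuote(dup[1L]), " (line ", line, ")")
  }
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids in header")
  rownames(m) <- ids
  m
}

#' Write a matrix as an id-column TSV
#'
#' @param m matrix with row and column names.
#' @param file output path.
#' @param idName header of the id column.
#' @export
writeExpressionMatrix <- function(m, file, idName = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- idName
  utils::write.table(d, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a probe-to-gene map (2-column TSV: probe_id, gene_id)
#'
#' @param file path.
#' @return data.frame with columns \code{probeId}, \code{geneId};
#'   duplicated pairs collapsed.
#' @export
readProbeGeneMap <- function(file) {
  d <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) != 2L) stop("probe map must have 2 columns, found ",
                          ncol(d))
  names(d) <- c("probeId", "geneId")
  unique(d)
}

#' Serialize / read a fitted reference model as versioned TSV
#'
#' One row per probe with the six mixture parameters and the fit status;
#' fallback probes append their sorted reference values in an extra
#' comma-separated column.
#'
#' @param model a \linkS4class{ReferenceModel}.
#' @param file path.
#' @return \code{readReferenceModel} returns a
#'   \linkS4class{ReferenceModel}.
#' @export
writeReferenceModel <- function(model, file) {
  stopifnot(is(model, "ReferenceModel"))
  p <- model@params
  p$ecdfValues <- vapply(p$probeId, function(id) {
    v <- model@ecdfValues[[id]]
    if (is.null(v)) "" else paste(format(v, digits = 17), collapse = ",")
  }, character(1))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# sigCircuits reference model v1", con)
  utils::write.table(p, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname writeReferenceModel
#' @export
readReferenceModel <- function(file) {
  header <- readLines(file, n = 1L)
  if (!startsWith(header, "# sigCircuits reference model"))
    stop("not a sigCircuits reference model file")
  d <- utils::read.delim(file, skip = 1L, stringsAsFactors = FALSE)
  ecdf <- list()
  fb <- which(d$fitStatus == "fallback_ecdf")
  for (i in fb)
    ecdf[[d$probeId[i]]] <- as.numeric(strsplit(d$ecdfValues[i],
                                                ",")[[1L]])
  d$ecdfValues <- NULL
  new("ReferenceModel", params = d, ecdfValues = ecdf)
}

#' Read a precomputed activation-probability matrix
#'
#' Same TSV layout as an expression matrix but all values must lie in
#' \[0, 1\].
#'
#' @param file path.
#' @param level what rows represent (default \code{"gene"}).
#' @return An \linkS4class{ActivationMatrix}.
#' @export
readActivationMatrix <- function(file, level = "gene") {
  m <- readExpressionMatrix(file)
  if (any(m < 0 | m > 1))
    stop("activation file contains values outside [0, 1]")
  ActivationMatrix(m, level)
}

# node attribute table for Cytoscape: per node, direction of the most
# significant circuit containing it
nodeAttributes <- function(graph, circuits, results) {
  dir <- rep("ns", nrow(graph@nodes))
  best <- rep(Inf, nrow(graph@nodes))
  names(dir) <- names(best) <- graph@nodes$nodeId
  for (cir in circuits) {
    row <- results[results$circuitId == cir@circuitId, ]
    if (!nrow(row)) next
    for (nd in nodeUniverse(cir)) {
      if (row$fdr[1L] < best[nd]) {
        best[nd] <- row$fdr[1L]
        dir[nd] <- row$direction[1L]
      }
    }
  }
  data.frame(nodeId = graph@nodes$nodeId, label = graph@nodes$label,
             kind = graph@nodes$kind, direction = dir,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full pathway-circuit analysis pipeline
#'
#' Drives every step from raw files (or in-memory objects) to result
#' tables on disk: parse KGML pathways, resolve the activation source
#' (exactly one of a reference matrix, a fitted reference model, or a
#' precomputed activation matrix — or declare the expression rows to be
#' probabilities already), summarize probes to genes and genes to nodes,
#' enumerate circuits, profile per-sample transmission probabilities,
#' test case vs control per circuit with BH FDR across all circuits of
#' the run, and summarize each pathway.
#'
#' Written artifacts: \code{circuits.tsv} (per-circuit test results),
#' \code{summary.tsv} (per-pathway summaries), per-pathway \code{.sif} and
#' \code{_nodes.tsv} Cytoscape files with up/down/ns significance
#' attributes, and \code{manifest.json} (package version, seed, config
#' echo, collected warnings).
#'
#' @param kgml character vector of KGML file paths, or of KGML XML
#'   strings.
#' @param expr expression matrix (probes/genes x samples) or TSV path.
#' @param design design data.frame (\code{sampleId}, \code{label}) or TSV
#'   path.
#' @param outDir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param controlLabel design label of the control class.
#' @param probeMap optional probe-to-gene map (data.frame or TSV path);
#'   when absent, expression rows are taken to be genes.
#' @param reference optional reference matrix or TSV path (mixture models
#'   are fitted on it).
#' @param referenceModel optional fitted \linkS4class{ReferenceModel} or
#'   model TSV path.
#' @param activation optional precomputed gene-level
#'   \linkS4class{ActivationMatrix} or TSV path.
#' @param rowsAreProbabilities set \code{TRUE} when \code{expr} already
#'   holds gene-level probabilities in \[0, 1\].
#' @param summarization probe-to-gene summary method, see
#'   [geneActivation()].
#' @param alpha FDR significance level.
#' @param maxPaths,maxPathLength circuit enumeration caps.
#' @param pathCap,mcDraws exact inclusion/exclusion cap and Monte-Carlo
#'   fallback draws.
#' @param seed seed for any stochastic fallback.
#' @return Invisibly, a list with \code{results} (circuit table),
#'   \code{summaries} (pathway table), \code{profiles},
#'   \code{activation}, \code{graphs}, \code{circuits},
#'   \code{manifest}.
#' @export
runPipeline <- function(kgml, expr, design, outDir = NULL,
                        controlLabel = "control", probeMap = NULL,
                        reference = NULL, referenceModel = NULL,
                        activation = NULL, rowsAreProbabilities = FALSE,
                        summarization = "percentile90", alpha = 0.05,
                        maxPaths = 1000L, maxPathLength = 30L,
                        pathCap = 20L, mcDraws = 1e5, seed = 1L) {
  warningsSeen <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) {
    warningsSeen <<- c(warningsSeen, sub("\n$", "", conditionMessage(m)))
    invokeRestart("muffleMessage")
  })

  if (is.character(expr)) expr <- readExpressionMatrix(expr)
  if (is.character(design)) design <- readDesign(design,
                                                 sampleIds = colnames(expr))
  if (is.character(probeMap)) probeMap <- readProbeGeneMap(probeMap)
  if (is.character(reference)) reference <- readExpressionMatrix(reference)
  if (is.character(referenceModel))
    referenceModel <- readReferenceModel(referenceModel)
  if (is.character(activation)) activation <- readActivationMatrix(activation)

  sources <- c(reference = !is.null(reference),
               referenceModel = !is.null(referenceModel),
               activation = !is.null(activation),
               rowsAreProbabilities = isTRUE(rowsAreProbabilities))
  if (sum(sources) != 1L)
    stop("exactly one activation source required; got: ",
         if (any(sources)) paste(names(sources)[sources], collapse = ", ")
         else "none")

  missingSamples <- setdiff(colnames(expr), design$sampleId)
  extraSamples <- setdiff(design$sampleId, colnames(expr))
  if (length(missingSamples) || length(extraSamples))
    stop("sample-id mismatch between expression and design; ",
         "expression-only: [", paste(missingSamples, collapse = ", "),
         "], design-only: [", paste(extraSamples, collapse = ", "), "]")

  # --- activation source -> gene-level activation matrix
  geneProbs <- collect({
    if (isTRUE(rowsAreProbabilities)) {
      if (any(expr < 0 | expr > 1))
        stop("rowsAreProbabilities set but values fall outside [0, 1]")
      ActivationMatrix(expr, "gene")
    } else if (!is.null(activation)) {
      activation
    } else {
      model <- if (!is.null(referenceModel)) referenceModel
               else fitReferenceModel(reference, seed = seed)
      probeProbs <- probeActivation(expr, model)
      if (!is.null(probeMap))
        geneActivation(probeProbs, probeMap, method = summarization)
      else ActivationMatrix(probeProbs@values, "gene")
    }
  })

  graphs <- list()
  circuitsByPathway <- list()
  profiles <- NULL
  stochasticFlags <- logical(0)
  circuitMeta <- NULL
  for (k in kgml) {
    g <- collect(parseKGML(k))
    graphs[[g@pathwayId]] <- g
    circ <- collect(enumerateCircuits(g, maxPaths = maxPaths,
                                      maxPathLength = maxPathLength))
    if (!length(circ)) {
      warningsSeen <- c(warningsSeen,
                        paste0("pathway ", g@pathwayId, " has no circuits"))
      circuitsByPathway[[g@pathwayId]] <- list()
      next
    }
    circuitsByPathway[[g@pathwayId]] <- circ
    nodeProbs <- collect(nodeActivation(geneProbs, g))
    prof <- collect(profileCircuits(circ, nodeProbs, pathCap = pathCap,
                                    mcDraws = mcDraws, seed = seed))
    stochasticFlags <- c(stochasticFlags, attr(prof, "stochastic"))
    profiles <- rbind(profiles, prof)
    circuitMeta <- rbind(circuitMeta, data.frame(
      pathwayId = g@pathwayId,
      circuitId = names(circ),
      receptor = vapply(circ, function(x) x@receptor, character(1)),
      effector = vapply(circ, function(x) x@effector, character(1)),
      nPaths = vapply(circ, function(x) length(x@paths), integer(1)),
      truncated = vapply(circ, function(x) x@truncated, logical(1)),
      stringsAsFactors = FALSE, row.names = NULL))
  }
  if (is.null(profiles))
    stop("no circuits found in any supplied pathway")

  results <- testCircuits(profiles, design, controlLabel = controlLabel,
                          alpha = alpha)
  results <- cbind(circuitMeta[match(results$circuitId,
                                     circuitMeta$circuitId),
                               c("pathwayId", "receptor", "effector",
                                 "nPaths", "truncated")],
                   results)
  results <- results[, c("pathwayId", "circuitId", "receptor", "effector",
                         "nPaths", "truncated", "meanCase", "meanControl",
                         "delta", "statistic", "pValue", "fdr",
                         "direction", "degenerate")]
  rownames(results) <- NULL

  summaries <- do.call(rbind, lapply(split(results, results$pathwayId),
                                     function(r)
    summarizePathway(r, alpha = alpha, pathwayId = r$pathwayId[1L])))
  rownames(summaries) <- NULL

  manifest <- list(
    package = "sigCircuits",
    version = as.character(utils::packageVersion("sigCircuits")),
    rVersion = as.character(getRversion()),
    seed = seed,
    config = list(controlLabel = controlLabel,
                  summarization = summarization, alpha = alpha,
                  maxPaths = maxPaths, maxPathLength = maxPathLength,
                  pathCap = pathCap, mcDraws = mcDraws,
                  activationSource = names(sources)[sources]),
    nPathways = length(graphs),
    nCircuits = nrow(results),
    stochasticCircuits = names(stochasticFlags)[stochasticFlags],
    warnings = warningsSeen)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeResultsTable(results, file.path(outDir, "circuits.tsv"))
    utils::write.table(summaries, file.path(outDir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (pid in names(graphs)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", pid)
      exportSIF(graphs[[pid]], file.path(outDir, paste0(safe, ".sif")))
      attrs <- nodeAttributes(graphs[[pid]], circuitsByPathway[[pid]],
                              results)
      utils::write.table(attrs,
                         file.path(outDir, paste0(safe, "_nodes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(results = results, summaries = summaries,
                 profiles = profiles, activation = geneProbs,
                 graphs = graphs, circuits = circuitsByPathway,
                 manifest = manifest))
}

#' Write / read a circuit results table as TSV
#'
#' Numeric columns are written with 15 significant digits so a write/read
#' round trip preserves values to at least 12 significant digits.
#'
#' @param results data.frame from [runPipeline()] or [testCircuits()].
#' @param file path.
#' @export
writeResultsTable <- function(results, file) {
  d <- results
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) format(x, digits = 15,
                                              scientific = TRUE,
                                              trim = TRUE))
  utils::write.table(d, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
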