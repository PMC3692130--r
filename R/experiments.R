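# Replicated validation experiments on the synthetic generator: type-I
# calibration under the null and planted-circuit recovery. The per-probe
# reference model is fitted once per experiment (the reference
# distribution is identical across replicates, mirroring the
# precomputed-distributions design); each replicate then draws a fresh
# study and runs the full analysis chain.

# one study through the analysis chain: posteriors -> gene -> node ->
# transmission profiles -> per-circuit tests
analyzeSyntheticStudy <- function(st, model, alpha = 0.05) {
  probeProbs <- probeActivation(st$expr, model)
  geneProbs <- geneActivation(probeProbs, st$probeMap,
                              method = "percentile90")
  nodeProbs <- nodeActivation(geneProbs, st$graph)
  prof <- profileCircuits(st$circuits, nodeProbs)
  testCircuits(prof, st$design, controlLabel = "control", alpha = alpha)
}

#' Type-I error calibration of the circuit test under the null
#'
#' Repeatedly draws case and control samples from the same generator (no
#' planted effect), runs the full analysis chain, and reports the
#' fraction of circuit tests with raw p at most \code{alphaRaw}. For a
#' calibrated test this fraction sits at (slightly below, given rank-test
#' discreteness) the nominal level.
#'
#' @param nReplicates number of replicate studies.
#' @param nCase,nControl class sizes per replicate.
#' @param nCopies number of gene-disjoint diamond components (circuits)
#'   per replicate study.
#' @param alphaRaw nominal level evaluated on raw p-values.
#' @param seed seed; replicate \code{r} draws with sample seed
#'   \code{seed + 20000 + r}.
#' @return list: \code{fraction} (overall fraction of raw p <=
#'   \code{alphaRaw}), \code{pValues} (matrix, circuits x replicates).
#' @export
nullCalibrationExperiment <- function(nReplicates = 1000L, nCase = 10L,
                                      nControl = 10L, nCopies = 8L,
                                      alphaRaw = 0.05, seed = 1L) {
  spec <- simulationSpec(template = "diamond",
                         templateParams = list(nCopies = nCopies),
                         nCase = nCase, nControl = nControl, seed = seed)
  st0 <- simulateStudy(spec, sampleSeed = seed + 10000L,
                       computeTruth = FALSE)
  model <- fitReferenceModel(st0$reference)
  pv <- vapply(seq_len(nReplicates), function(r) {
    st <- simulateStudy(spec, sampleSeed = seed + 20000L + r,
                        computeTruth = FALSE, drawReference = FALSE)
    analyzeSyntheticStudy(st, model)$pValue
  }, numeric(length(st0$circuits)))
  pv <- matrix(pv, nrow = length(st0$circuits))
  rownames(pv) <- names(st0$circuits)
  list(fraction = mean(pv <= alphaRaw), pValues = pv)
}

#' Recovery of a planted differential circuit
#'
#' Plants a presence log-odds shift on every gene of one circuit (the
#' other circuits are gene-disjoint), replicates the study, and reports
#' how often the planted circuit is called significant at
#' \code{fdr <= alpha} and how often unperturbed circuits are.
#'
#' @inheritParams nullCalibrationExperiment
#' @param effect log-odds shift applied to the planted circuit's genes in
#'   cases (negative = loss of signal transmission).
#' @param alpha FDR level for calling a circuit significant.
#' @return list: \code{recovery} (fraction of replicates flagging the
#'   planted circuit), \code{offTarget} (fraction of unperturbed
#'   circuit-replicates flagged), \code{truth} (ground-truth transmission
#'   table of the generator).
#' @export
plantedRecoveryExperiment <- function(nReplicates = 200L, nCase = 15L,
                                      nControl = 15L, nCopies = 4L,
                                      effect = -3, alpha = 0.05,
                                      seed = 1L) {
  spec <- simulationSpec(template = "diamond",
                         templateParams = list(nCopies = nCopies),
                         nCase = nCase, nControl = nControl,
                         planted = list(list(circuit = 1L,
                                             effect = effect)),
                         seed = seed)
  st0 <- simulateStudy(spec, sampleSeed = seed + 10000L)
  model <- fitReferenceModel(st0$reference)
  plantedId <- st0$truth$circuitId[st0$truth$planted]
  hits <- logical(nReplicates)
  offTarget <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    st <- simulateStudy(spec, sampleSeed = seed + 20000L + r,
                        computeTruth = FALSE, drawReference = FALSE)
    res <- analyzeSyntheticStudy(st, model, alpha = alpha)
    sig <- res$fdr <= alpha
    hits[r] <- sig[res$circuitId == plantedId]
    offTarget[r] <- mean(sig[res$circuitId != plantedId])
  }
  list(recovery = mean(hits), offTarget = mean(offTarget),
       truth = st0$truth)
}
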