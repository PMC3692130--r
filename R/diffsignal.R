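# Differential circuit analysis: per-circuit two-sided rank-sum test on
# per-sample transmission probabilities, BH FDR across circuits, and a
# per-pathway summary. Transmission probabilities are bounded in [0,1]
# and far from normal, so the Wilcoxon rank-sum test is the conventional
# choice; the test function is pluggable through `testFun`.

#' Read a case/control design file
#'
#' Accepts a 2-column TSV (\code{sample_id<TAB>label}, no header) or a
#' 1-column file of one label per line in sample order (then
#' \code{sampleIds} must be supplied).
#'
#' @param file path.
#' @param sampleIds sample ids, required for 1-column files.
#' @return data.frame with columns \code{sampleId}, \code{label}.
#' @export
readDesign <- function(file, sampleIds = NULL) {
  d <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) == 1L) {
    if (is.null(sampleIds))
      stop("1-column design file needs explicit sample ids")
    if (length(sampleIds) != nrow(d))
      stop("design file has ", nrow(d), " labels for ",
           length(sampleIds), " samples")
    d <- data.frame(sampleId = sampleIds, label = d[[1L]],
                    stringsAsFactors = FALSE)
  } else if (ncol(d) == 2L) {
    names(d) <- c("sampleId", "label")
  } else stop("design file must have 1 or 2 columns, found ", ncol(d))
  if (anyDuplicated(d$sampleId))
    stop("duplicated sample id(s) in design: ",
         paste(unique(d$sampleId[duplicated(d$sampleId)]), collapse = ", "))
  if (length(unique(d$label)) != 2L)
    stop("design must contain exactly two class labels, found: ",
         paste(unique(d$label), collapse = ", "))
  d
}

#' Rank-sum test of one circuit's transmission profile
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test comparing per-sample
#' transmission probabilities between cases and controls. The exact null
#' distribution is used when the smaller class has at most 8 samples and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Profiles constant across both classes get
#' p = 1 and a degenerate flag rather than an error.
#'
#' @param values named numeric vector of per-sample transmission
#'   probabilities.
#' @param design data.frame with \code{sampleId}, \code{label} covering
#'   all samples.
#' @param controlLabel which design label is the control class.
#' @param minPerClass floor on the class sizes.
#' @return list with \code{statistic} (Mann-Whitney W of case vs
#'   control), \code{p.value}, \code{meanCase}, \code{meanControl},
#'   \code{delta} and \code{degenerate}.
#' @export
circuitTest <- function(values, design, controlLabel = "control",
                        minPerClass = 3L) {
  miss <- setdiff(names(values), design$sampleId)
  if (length(miss))
    stop("samples missing from design: ", paste(miss, collapse = ", "))
  lab <- design$label[match(names(values), design$sampleId)]
  if (!controlLabel %in% lab)
    stop("control label ", sQuote(controlLabel), " not present in design")
  ctl <- values[lab == controlLabel]
  cas <- values[lab != controlLabel]
  if (length(ctl) < minPerClass || length(cas) < minPerClass)
    stop("need >= ", minPerClass, " samples per class (",
         length(cas), " case, ", length(ctl), " control)")
  res <- list(meanCase = mean(cas), meanControl = mean(ctl),
              delta = mean(cas) - mean(ctl))
  if (length(unique(c(cas, ctl))) == 1L) {
    res$statistic <- length(cas) * length(ctl) / 2
    res$p.value <- 1
    res$degenerate <- TRUE
    return(res)
  }
  ties <- anyDuplicated(c(cas, ctl)) > 0L
  exact <- min(length(cas), length(ctl)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    cas, ctl, alternative = "two.sided", exact = exact,
    correct = TRUE))
  res$statistic <- unname(wt$statistic)
  res$p.value <- min(1, wt$p.value)
  res$degenerate <- FALSE
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (\code{p(i) * m / i} with monotone enforcement,
#' capped at 1), delegated to [stats::p.adjust()] after range validation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @examples
#' adjustFDR(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
adjustFDR <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Test all circuits of a transmission profile matrix
#'
#' Runs [circuitTest()] per circuit, adjusts p-values across all circuits
#' with [adjustFDR()], and assigns each circuit a direction: \code{"up"}
#' (case transmission higher) or \code{"down"} when the FDR is at most
#' \code{alpha}, \code{"ns"} otherwise.
#'
#' @param profiles numeric matrix, circuits x samples (from
#'   [profileCircuits()]).
#' @param design data.frame with \code{sampleId}, \code{label}.
#' @param controlLabel control class label.
#' @param alpha FDR significance level.
#' @param minPerClass floor on class sizes.
#' @return data.frame with one row per circuit: \code{circuitId},
#'   \code{meanCase}, \code{meanControl}, \code{delta}, \code{statistic},
#'   \code{pValue}, \code{fdr}, \code{direction}, \code{degenerate}.
#' @export
testCircuits <- function(profiles, design, controlLabel = "control",
                         alpha = 0.05, minPerClass = 3L) {
  extra <- setdiff(colnames(profiles), design$sampleId)
  if (length(extra))
    stop("profiled samples missing from design: ",
         paste(extra, collapse = ", "))
  rows <- lapply(rownames(profiles), function(cid) {
    r <- circuitTest(profiles[cid, ], design, controlLabel,
                     minPerClass)
    data.frame(circuitId = cid, meanCase = r$meanCase,
               meanControl = r$meanControl, delta = r$delta,
               statistic = r$statistic, pValue = r$p.value,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- adjustFDR(res$pValue)
  res$direction <- ifelse(res$fdr > alpha, "ns",
                          ifelse(res$delta > 0, "up", "down"))
  res[, c("circuitId", "meanCase", "meanControl", "delta", "statistic",
          "pValue", "fdr", "direction", "degenerate")]
}

#' Summarize circuit test results for one pathway
#'
#' Counts circuits significantly up- or down-regulated at
#' \code{fdr <= alpha} and computes a global activity score: the signed
#' fraction \code{(nUp - nDown) / nCircuits}, bounded in \[-1, 1\].
#'
#' @param results data.frame from [testCircuits()], all rows belonging to
#'   one pathway.
#' @param alpha FDR significance level.
#' @param pathwayId optional id recorded in the summary.
#' @return One-row data.frame: \code{pathwayId}, \code{nCircuits},
#'   \code{nSignificantUp}, \code{nSignificantDown},
#'   \code{globalActivityScore}.
#' @export
summarizePathway <- function(results, alpha = 0.05, pathwayId = NA) {
  if (!nrow(results)) stop("empty result list")
  sig <- results$fdr <= alpha
  up <- sum(sig & results$delta > 0)
  down <- sum(sig & results$delta < 0)
  data.frame(pathwayId = pathwayId, nCircuits = nrow(results),
             nSignificantUp = up, nSignificantDown = down,
             globalActivityScore = (up - down) / nrow(results),
             stringsAsFactors = FALSE)
}
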