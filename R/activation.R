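# Presence/absence modeling: per-probe two-component normal mixture on
# log2 reference intensities, fitted by EM. The component with the larger
# mean is "present"; the posterior of that component given an expression
# value is the probe's activation probability.

# one EM run from a given start; tolerance on the log-likelihood,
# <= maxIter iterations; NULL when it degenerates or fails to converge
runEM <- function(x, mu, sds, w, tol = 1e-8, maxIter = 500L,
                  sdFloor = 1e-3) {
  n <- length(x)
  ll <- -Inf
  for (iter in seq_len(maxIter)) {
    d1 <- w[1L] * stats::dnorm(x, mu[1L], sds[1L])
    d2 <- w[2L] * stats::dnorm(x, mu[2L], sds[2L])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    llNew <- sum(log(tot))
    if (is.finite(llNew) && llNew - ll < tol * (abs(ll) + 1) &&
        iter > 1L)
      return(list(mu = mu, sds = sds, w = w, ll = llNew))
    ll <- llNew
    n1 <- sum(r1); n2 <- sum(r2)
    if (min(n1, n2) < .Machine$double.eps) return(NULL)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sds <- sqrt(c(sum(r1 * (x - mu[1L])^2) / n1,
                  sum(r2 * (x - mu[2L])^2) / n2))
    w <- c(n1, n2) / n
    if (any(sds < sdFloor)) return(NULL)
  }
  NULL  # no convergence within maxIter
}

# Two-component mixture fit for one probe. Deterministic multi-start EM:
# one start from the 25th/75th percentiles and one from a
# midpoint-threshold split (which reaches minority presence/absence
# components that the quartile start can miss); the converged run with
# the higher log-likelihood wins. The fit is only accepted as a
# presence/absence model when the components are separated (Ashman's
# D = |mu2-mu1| / sqrt((s1^2+s2^2)/2) >= 2, the usual bimodality bar);
# otherwise the probe falls back to its empirical distribution.
fitProbeMixture <- function(x, tol = 1e-8, maxIter = 500L,
                            weightFloor = 0.01, sdFloor = 1e-3,
                            minSeparationD = 2) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7)
  s0 <- stats::sd(x)
  if (!is.finite(s0) || s0 < sdFloor || q[1L] == q[2L])
    return(list(status = "fallback_ecdf"))
  starts <- list(list(mu = as.numeric(q), sds = c(s0, s0) / 2,
                      w = c(0.5, 0.5)))
  thr <- mean(stats::quantile(x, c(0.01, 0.99), type = 7))
  lo <- x[x < thr]; hi <- x[x >= thr]
  if (length(lo) >= 2L && length(hi) >= 2L && stats::sd(lo) > 0 &&
      stats::sd(hi) > 0)
    starts <- c(starts, list(list(
      mu = c(mean(lo), mean(hi)),
      sds = pmax(c(stats::sd(lo), stats::sd(hi)), s0 / 20),
      w = pmax(c(length(lo), length(hi)) / length(x), 0.02))))
  best <- NULL
  for (st in starts) {
    f <- runEM(x, st$mu, st$sds, st$w, tol = tol, maxIter = maxIter,
               sdFloor = sdFloor)
    if (!is.null(f) && (is.null(best) || f$ll > best$ll)) best <- f
  }
  if (is.null(best)) return(list(status = "fallback_ecdf"))
  mu <- best$mu; sds <- best$sds; w <- best$w
  sepD <- abs(mu[2L] - mu[1L]) / sqrt(mean(sds^2))
  if (any(w < weightFloor) || any(sds < sdFloor) || mu[1L] == mu[2L] ||
      sepD < minSeparationD)
    return(list(status = "fallback_ecdf"))
  ord <- order(mu)  # smaller mean = absent
  list(status = "ok",
       par = c(wAbsent = w[ord[1L]], meanAbsent = mu[ord[1L]],
               sdAbsent = sds[ord[1L]], wPresent = w[ord[2L]],
               meanPresent = mu[ord[2L]], sdPresent = sds[ord[2L]]))
}

#' Fit per-probe presence/absence models on a reference compendium
#'
#' For each probe (row) of a log2-scale reference expression matrix, fits
#' a two-component normal mixture by deterministic multi-start EM (a
#' quartile start plus a midpoint-threshold start that reaches minority
#' components; best log-likelihood wins); the component with the larger
#' mean is labeled "present". Degenerate or unidentifiable fits (a
#' component weight below 0.01, a component sd below 1e-3, no
#' convergence within 500 iterations, or component separation below
#' Ashman's D = 2 — i.e. no real bimodality) fall back to the probe's
#' empirical distribution, later used through a mid-rank ECDF.
#'
#' @param reference numeric matrix, probes x reference samples, log2
#'   scale; needs row names.
#' @param seed kept for interface stability; the quartile-initialized EM
#'   is deterministic and draws no random numbers.
#' @param minSamples minimum reference samples required per probe.
#' @return A \linkS4class{ReferenceModel}.
#' @examples
#' set.seed(1)
#' ref <- rbind(p1 = c(rnorm(100, 6), rnorm(100, 10)))
#' fitReferenceModel(ref)
#' @export
fitReferenceModel <- function(reference, seed = 1L, minSamples = 20L) {
  if (is.null(rownames(reference)))
    stop("reference matrix needs probe row names")
  if (any(!is.finite(reference)))
    stop("non-finite values in reference matrix")
  if (ncol(reference) < minSamples)
    stop("probe ", rownames(reference)[1L], ": ", ncol(reference),
         " reference samples < required floor ", minSamples)
  probes <- rownames(reference)
  fits <- lapply(seq_along(probes), function(i)
    fitProbeMixture(reference[i, ]))
  status <- vapply(fits, `[[`, character(1), "status")
  par <- t(vapply(fits, function(f) {
    if (f$status == "ok") f$par else rep(NA_real_, 6L)
  }, numeric(6L)))
  params <- data.frame(probeId = probes, par, fitStatus = status,
                       stringsAsFactors = FALSE)
  colnames(params)[2:7] <- c("wAbsent", "meanAbsent", "sdAbsent",
                             "wPresent", "meanPresent", "sdPresent")
  rownames(params) <- NULL
  fb <- which(status == "fallback_ecdf")
  ecdfValues <- lapply(fb, function(i) sort(reference[i, ]))
  names(ecdfValues) <- probes[fb]
  if (length(fb))
    message(length(fb), " probe(s) fell back to the empirical ",
            "distribution")
  new("ReferenceModel", params = params, ecdfValues = ecdfValues)
}

# mid-rank empirical cumulative fraction; ties get their average rank
midRankEcdf <- function(values, ref) {
  n <- length(ref)
  vapply(values, function(v)
    (sum(ref < v) + 0.5 * sum(ref == v)) / n, numeric(1))
}

#' Convert expression values into probe activation probabilities
#'
#' For mixture-fitted probes the activation probability is the posterior
#' probability of the "present" component given the observed value; for
#' fallback probes it is the mid-rank empirical cumulative fraction of the
#' value within the stored reference values.
#'
#' @param expr numeric matrix (probes x samples, log2 scale) with row and
#'   column names.
#' @param model a \linkS4class{ReferenceModel} covering every probe of
#'   \code{expr}.
#' @return An \linkS4class{ActivationMatrix} at probe level, same shape
#'   as \code{expr}.
#' @export
probeActivation <- function(expr, model) {
  stopifnot(is(model, "ReferenceModel"))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs row and column names")
  if (any(!is.finite(expr))) stop("non-finite expression values")
  p <- model@params
  idx <- match(rownames(expr), p$probeId)
  if (anyNA(idx))
    stop("probes missing from the reference model: ",
         paste(rownames(expr)[is.na(idx)], collapse = ", "))
  out <- matrix(NA_real_, nrow(expr), ncol(expr),
                dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    r <- idx[i]
    x <- expr[i, ]
    if (p$fitStatus[r] == "ok") {
      # posterior on the log scale for numerical stability far in the tails
      la <- log(p$wAbsent[r]) +
        stats::dnorm(x, p$meanAbsent[r], p$sdAbsent[r], log = TRUE)
      lp <- log(p$wPresent[r]) +
        stats::dnorm(x, p$meanPresent[r], p$sdPresent[r], log = TRUE)
      out[i, ] <- 1 / (1 + exp(la - lp))
    } else {
      out[i, ] <- midRankEcdf(x, model@ecdfValues[[p$probeId[r]]])
    }
  }
  ActivationMatrix(clamp01(out), "probe")
}

#' Summarize probe activation probabilities to gene level
#'
#' Collapses the probes mapping to each gene into one activation
#' probability per gene and sample. The default is the 90th percentile of
#' the probe probabilities (reduces false positives from single erroneous
#' probe measurements while staying near the most-active evidence);
#' \code{mean}, \code{median} and \code{max} are also available.
#' Percentiles interpolate linearly between order statistics
#' (h = 0.9(n-1), zero-based).
#'
#' @param probeProbs \linkS4class{ActivationMatrix} at probe level.
#' @param map data.frame with columns \code{probeId}, \code{geneId}
#'   (many-to-many allowed; duplicate pairs are collapsed).
#' @param method one of \code{"percentile90"}, \code{"mean"},
#'   \code{"median"}, \code{"max"}.
#' @param unmapped \code{"warn"} drops genes with no probes in
#'   \code{probeProbs} with a warning; \code{"error"} stops.
#' @return An \linkS4class{ActivationMatrix} at gene level.
#' @examples
#' m <- matrix(c(0.2, 0.5, 0.9), 3, 1,
#'             dimnames = list(c("p1", "p2", "p3"), "s1"))
#' map <- data.frame(probeId = c("p1", "p2", "p3"), geneId = "g1")
#' activationValues(geneActivation(ActivationMatrix(m, "probe"), map))
#' @export
geneActivation <- function(probeProbs, map,
                           method = c("percentile90", "mean", "median",
                                      "max"),
                           unmapped = c("warn", "error")) {
  method <- match.arg(method)
  unmapped <- match.arg(unmapped)
  stopifnot(is(probeProbs, "ActivationMatrix"))
  if (!all(c("probeId", "geneId") %in% names(map)))
    stop("map needs columns probeId, geneId")
  map <- unique(map[, c("probeId", "geneId")])
  v <- probeProbs@values
  map <- map[map$probeId %in% rownames(v), , drop = FALSE]
  genes <- unique(map$geneId)
  if (!length(genes)) stop("no gene has a measured probe")
  summarize <- switch(method,
    percentile90 = function(m) percentileColwise(m, 0.9),
    mean = function(m) colMeans(m),
    median = function(m) percentileColwise(m, 0.5),
    max = function(m) apply(m, 2L, max))
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  for (g in genes) {
    probes <- map$probeId[map$geneId == g]
    out[g, ] <- summarize(v[probes, , drop = FALSE])
  }
  ActivationMatrix(clamp01(out), "gene")
}

#' Summarize gene activation probabilities to pathway-node level
#'
#' For a node of alternative (interchangeable) proteins the node
#' probability is the highest member probability; for a protein complex
#' every member must be present, so the node probability is the lowest
#' member probability.
#'
#' @param geneProbs \linkS4class{ActivationMatrix} at gene level.
#' @param graph a \linkS4class{PathwayGraph}.
#' @param missingMembers \code{"warn"}: a node with some member genes
#'   missing from \code{geneProbs} is summarized over its observed members
#'   with a warning; a node with no observed member is always an error.
#'   \code{"error"}: any missing member stops.
#' @return An \linkS4class{ActivationMatrix} at node level, rows indexed
#'   by node id.
#' @export
nodeActivation <- function(geneProbs, graph,
                           missingMembers = c("warn", "error")) {
  missingMembers <- match.arg(missingMembers)
  stopifnot(is(geneProbs, "ActivationMatrix"), is(graph, "PathwayGraph"))
  v <- geneProbs@values
  nd <- graph@nodes
  out <- matrix(NA_real_, nrow(nd), ncol(v),
                dimnames = list(nd$nodeId, colnames(v)))
  for (i in seq_len(nrow(nd))) {
    mem <- nd$members[[i]]
    obs <- intersect(mem, rownames(v))
    if (!length(obs))
      stop("node ", nd$nodeId[i], " has no member gene in the ",
           "activation matrix (members: ", paste(mem, collapse = ", "),
           ")")
    if (length(obs) < length(mem)) {
      msg <- paste0("node ", nd$nodeId[i], ": ",
                    length(mem) - length(obs),
                    " member gene(s) missing; summarizing over observed ",
                    "members")
      if (missingMembers == "error") stop(msg) else warning(msg,
                                                            call. = FALSE)
    }
    sub <- v[obs, , drop = FALSE]
    out[i, ] <- if (nd$kind[i] == "complex") apply(sub, 2L, min)
                else apply(sub, 2L, max)
  }
  ActivationMatrix(out, "node")
}
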