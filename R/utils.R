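# internal helpers

# evaluate expr under a temporary RNG state; global seed restored after
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# percentile with linear interpolation between order statistics,
# h = q*(n-1) zero-based (stats::quantile type 7)
percentileInterp <- function(x, q) {
  unname(stats::quantile(x, probs = q, type = 7, names = FALSE))
}

# column-wise version of percentileInterp, vectorized for hot loops
percentileColwise <- function(m, q) {
  n <- nrow(m)
  if (n == 1L) return(m[1L, ])
  sm <- apply(m, 2L, sort, method = "radix")
  h <- q * (n - 1)
  lo <- floor(h)
  sm[lo + 1L, ] + (h - lo) * (sm[min(lo + 2L, n), ] - sm[lo + 1L, ])
}

# clamp tiny floating-point excursions outside [0,1]
clamp01 <- function(x, tol = 1e-12) {
  x[x < 0 & x > -tol] <- 0
  x[x > 1 & x < 1 + tol] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
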