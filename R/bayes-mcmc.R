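#' MCMC settings constructor
#'
#' Defaults mirror the analysis schedule used throughout the package: 3
#' chains, 1000-iteration burn-in, 10000 sampling iterations with every third
#' draw retained (`floor(nIter / thin)` retained draws per chain).
#'
#' @param nChains,burnIn,nIter,thin,seed positive integers.
#' @return an [McmcSettings-class].
#' @export
mcmcSettings <- function(nChains = 3L, burnIn = 1000L, nIter = 10000L,
                         thin = 3L, seed = 1L) {
  new("McmcSettings", nChains = as.integer(nChains),
      burnIn = as.integer(burnIn), nIter = as.integer(nIter),
      thin = as.integer(thin), seed = as.integer(seed))
}

#' Prior specification constructor
#'
#' @param coefMean,coefPrecision normal prior on location / regression
#'   coefficients (default mean 0, precision tau = 1e-6, i.e. essentially
#'   flat).
#' @param precisionShape,precisionRate gamma prior on residual precisions
#'   (default shape = rate = 0.01).
#' @return a [PriorSpec-class].
#' @export
priorSpec <- function(coefMean = 0, coefPrecision = 1e-6,
                      precisionShape = 0.01, precisionRate = 0.01) {
  new("PriorSpec", coefMean = coefMean, coefPrecision = coefPrecision,
      precisionShape = precisionShape, precisionRate = precisionRate)
}

# Assemble a ChainSet from per-chain draw matrices.
chainSet <- function(draws, paramNames, logLik = list(), logLikFun = NULL) {
  draws <- lapply(draws, function(d) {
    colnames(d) <- paramNames
    d
  })
  new("ChainSet", draws = draws, paramNames = paramNames, logLik = logLik,
      logLikFun = logLikFun)
}

#' @describeIn ChainSet-class number of chains and retained draws.
#' @param object a ChainSet.
#' @export
setMethod("show", "ChainSet", function(object) {
  cat(sprintf("ChainSet: %d chain(s) x %d retained draws x %d parameter(s)\n",
              length(object@draws), nrow(object@draws[[1]]),
              length(object@paramNames)))
  cat("  parameters:", paste(object@paramNames, collapse = ", "), "\n")
})

# All chains stacked into one matrix.
pooledDraws <- function(chains) do.call(rbind, chains@draws)

#' Posterior summaries from pooled draws
#'
#' For each parameter: the posterior median (`pm`), the 95% equal-tail
#' probability interval (2.5th / 97.5th percentiles) and the tail posterior
#' probabilities that the parameter is greater / less than zero.
#'
#' @param x a [ChainSet-class] (pooled across chains) or a draws matrix.
#' @return data.frame with columns parameter, pm, lower, upper, pp_gt0,
#'   pp_lt0.
#' @export
setMethod("summarizePosterior", "ChainSet", function(x)
  summarizeDrawMatrix(pooledDraws(x)))

#' @rdname summarizePosterior-ChainSet-method
#' @export
setMethod("summarizePosterior", "matrix", function(x)
  summarizeDrawMatrix(x))

summarizeDrawMatrix <- function(m) {
  out <- do.call(rbind, lapply(seq_len(ncol(m)), function(j)
    drawSummary(m[, j])))
  data.frame(parameter = colnames(m) %||% paste0("par", seq_len(ncol(m))),
             out, row.names = NULL)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free R-hat: with W the mean within-chain variance and B/n
#' the variance of chain means, `R = sqrt(((n-1)/n * W + B/n) / W)`, floored
#' at 1 (identical chains give B = 0 and would otherwise report
#' sqrt((n-1)/n) < 1).
#'
#' @param x a [ChainSet-class] with >= 2 chains of equal length.
#' @return named numeric vector of R-hat values per parameter.
#' @export
setMethod("gelmanRubin", "ChainSet", function(x) {
  if (length(x@draws) < 2) stop("Gelman-Rubin requires >= 2 chains")
  n <- nrow(x@draws[[1]])
  vapply(seq_along(x@paramNames), function(j) {
    mat <- vapply(x@draws, function(d) d[, j], numeric(n))
    W <- mean(apply(mat, 2, stats::var))
    B_over_n <- stats::var(colMeans(mat))
    if (W == 0) return(1)
    max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
  }, 0, USE.NAMES = FALSE) -> r
  names(r) <- x@paramNames
  r
})

#' Effective sample size
#'
#' `ESS = n / (1 + 2 * sum rho_k)` per chain, with autocorrelations summed
#' under Geyer's initial-positive rule (consecutive lag pairs are added while
#' their sum stays positive), then summed over chains. A constant chain has
#' undefined autocorrelation and reports 0 with a warning.
#'
#' @param x a [ChainSet-class].
#' @return named numeric vector of ESS values per parameter.
#' @export
setMethod("effectiveSampleSize", "ChainSet", function(x) {
  ess <- vapply(seq_along(x@paramNames), function(j) {
    sum(vapply(x@draws, function(d) essVector(d[, j]), 0))
  }, 0)
  names(ess) <- x@paramNames
  ess
})

essVector <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) {
    warning("constant chain: effective sample size reported as 0")
    return(0)
  }
  rho <- as.numeric(stats::acf(v, lag.max = min(n - 1, 2000),
                               plot = FALSE)$acf) # rho[1] = lag 0 = 1
  tau <- 0
  k <- 1
  while (k < length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  tau <- max(1, tau - 1)
  min(n, n / tau)
}

#' Deviance information criterion
#'
#' Spiegelhalter's DIC from per-draw log-likelihoods: `Dbar` is the posterior
#' mean deviance, `pD = Dbar - D(theta_bar)` the effective number of
#' parameters (deviance evaluated at the posterior means of the sampled
#' parameters) and `DIC = Dbar + pD`.
#'
#' @param x a [ChainSet-class] carrying per-draw log-likelihoods and a
#'   log-likelihood function.
#' @return named numeric vector: DIC, pD, Dbar.
#' @export
setMethod("mcmcDic", "ChainSet", function(x) {
  if (!length(x@logLik) || is.null(x@logLikFun))
    stop("ChainSet carries no log-likelihood; DIC unavailable")
  ll <- unlist(x@logLik)
  dbar <- mean(-2 * ll)
  thetaBar <- colMeans(pooledDraws(x))
  names(thetaBar) <- x@paramNames
  dhat <- -2 * x@logLikFun(thetaBar)
  pd <- dbar - dhat
  c(DIC = dbar + pd, pD = pd, Dbar = dbar)
})

#' Export a ChainSet as columnar TSV
#'
#' One row per (chain, iteration, parameter) triple, for external
#' diagnostics.
#'
#' @param chains a [ChainSet-class].
#' @param path output file.
#' @export
writeChains <- function(chains, path) {
  rows <- do.call(rbind, lapply(seq_along(chains@draws), function(ch) {
    d <- chains@draws[[ch]]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(d)), ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
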