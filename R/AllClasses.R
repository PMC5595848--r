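#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' OtuExperiment: an OTU count table with taxonomy and sample metadata
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with OTUs as rows and
#' samples as columns. The `"counts"` assay holds non-negative integer counts,
#' `rowData()` carries the taxonomy lineage string (`lineage`) plus one column
#' per parsed rank, and `colData()` carries per-sample covariates (sample
#' type, population, plant, age, weight, survival).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(m - round(m)) > 1e-8)) msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "OTU ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!"lineage" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a 'lineage' column")
  if (length(msg)) msg else TRUE
})

#' ChainSet: raw MCMC output
#'
#' Holds retained post-burn-in draws from one or more chains, the per-draw
#' log-likelihood (when the model provides it) and a log-likelihood function
#' used to evaluate the deviance at the posterior mean for DIC.
#'
#' @slot draws list of per-chain matrices (retained iterations x parameters).
#' @slot paramNames character vector of parameter names.
#' @slot logLik list of per-chain numeric vectors of log-likelihood values
#'   (may be empty for models without a likelihood).
#' @slot logLikFun function mapping a named parameter vector to a
#'   log-likelihood, or NULL.
#' @export
setClass("ChainSet",
  representation(draws = "list", paramNames = "character",
                 logLik = "list", logLikFun = "functionOrNULL"))

setValidity("ChainSet", function(object) {
  msg <- character()
  if (!length(object@draws)) msg <- c(msg, "at least one chain required")
  nc <- vapply(object@draws, ncol, 0L)
  if (length(unique(nc)) > 1) msg <- c(msg, "chains disagree on parameter count")
  if (length(nc) && nc[1] != length(object@paramNames))
    msg <- c(msg, "paramNames length must match draw columns")
  if (any(!vapply(object@draws, function(d) all(is.finite(d)), TRUE)))
    msg <- c(msg, "draws must be finite")
  if (length(object@logLik) && length(object@logLik) != length(object@draws))
    msg <- c(msg, "logLik must have one vector per chain")
  if (length(msg)) msg else TRUE
})

#' McmcSettings: chain schedule
#'
#' Defaults follow a three-chain schedule with a 1000-iteration burn-in,
#' 10000 sampling iterations and every third draw retained.
#'
#' @slot nChains,burnIn,nIter,thin,seed integers.
#' @export
setClass("McmcSettings",
  representation(nChains = "integer", burnIn = "integer", nIter = "integer",
                 thin = "integer", seed = "integer"),
  prototype(nChains = 3L, burnIn = 1000L, nIter = 10000L, thin = 3L,
            seed = 1L))

setValidity("McmcSettings", function(object) {
  v <- c(object@nChains, object@burnIn, object@nIter, object@thin)
  if (any(v < 1L)) "all settings must be positive integers" else TRUE
})

#' PriorSpec: priors for the Bayesian models
#'
#' Diffuse defaults: Normal(0, 1/1e-6) on location/regression coefficients and
#' gamma(shape = 0.01, rate = 0.01) on precisions.
#'
#' @slot coefMean,coefPrecision,precisionShape,precisionRate numerics.
#' @export
setClass("PriorSpec",
  representation(coefMean = "numeric", coefPrecision = "numeric",
                 precisionShape = "numeric", precisionRate = "numeric"),
  prototype(coefMean = 0, coefPrecision = 1e-6, precisionShape = 0.01,
            precisionRate = 0.01))

setValidity("PriorSpec", function(object) {
  if (object@coefPrecision <= 0 || object@precisionShape <= 0 ||
      object@precisionRate <= 0)
    "precisions and gamma parameters must be > 0" else TRUE
})

#' GroupModelFit: per-group normal model with unequal variances
#'
#' @slot groups group labels.
#' @slot summary data.frame of posterior summaries for each group mean and
#'   standard deviation.
#' @slot chains the underlying [ChainSet].
#' @export
setClass("GroupModelFit",
  representation(groups = "character", summary = "data.frame",
                 chains = "ChainSet"))

#' RegressionFit: Bayesian linear or logistic regression
#'
#' @slot coefficients data.frame of posterior summaries per coefficient (and
#'   residual sigma for linear models).
#' @slot dic named numeric: DIC, pD, Dbar.
#' @slot chains the underlying [ChainSet].
#' @slot family "gaussian" or "binomial".
#' @slot design the design matrix used (including intercept).
#' @export
setClass("RegressionFit",
  representation(coefficients = "data.frame", dic = "numeric",
                 chains = "ChainSet", family = "character",
                 design = "matrix"))

#' OrdinationResult: PCA or PCoA scores
#'
#' @slot scores samples x axes matrix.
#' @slot explained fraction of variance (PCA) or of the positive-eigenvalue
#'   sum (PCoA) per retained axis.
#' @slot eigenvalues all eigenvalues, including any negative PCoA eigenvalues.
#' @slot method "pca_chord" or "pcoa_bray".
#' @slot loadings OTU loadings (PCA only) or NULL.
#' @export
setClass("OrdinationResult",
  representation(scores = "matrix", explained = "numeric",
                 eigenvalues = "numeric", method = "character",
                 loadings = "matrixOrNULL"))

setValidity("OrdinationResult", function(object) {
  e <- object@explained
  if (length(e) && (any(e < -1e-12) || any(e > 1 + 1e-12) ||
                    any(diff(e) > 1e-12)))
    "explained fractions must be non-increasing and in [0, 1]" else TRUE
})

#' DaFit: multinomial-Dirichlet relative-abundance posteriors per group
#'
#' @slot groups group labels.
#' @slot alphaPost groups x OTUs matrix of posterior Dirichlet parameters
#'   (prior alpha0 + within-group count sums).
#' @slot piDraws list (per group) of draws x OTUs matrices of relative
#'   abundance vectors.
#' @slot summary per-group, per-OTU posterior medians and 95% ETPIs.
#' @slot alpha0 prior concentration.
#' @export
setClass("DaFit",
  representation(groups = "character", alphaPost = "matrix",
                 piDraws = "list", summary = "data.frame",
                 alpha0 = "numeric"))

setValidity("DaFit", function(object) {
  msg <- character()
  if (nrow(object@alphaPost) != length(object@groups))
    msg <- c(msg, "one alphaPost row per group required")
  ok <- vapply(object@piDraws, function(p)
    max(abs(rowSums(p) - 1)) < 1e-8, TRUE)
  if (!all(ok)) msg <- c(msg, "every pi draw must sum to 1")
  if (length(msg)) msg else TRUE
})

#' PpRmseResult: posterior-predictive RMSE model comparison
#'
#' @slot rmseFull,rmseNull per-draw posterior-predictive RMSE values under
#'   the group-specific (full) and pooled (null) models.
#' @slot ppFullBetter Monte-Carlo estimate of Pr(RMSE_full < RMSE_null),
#'   paired by draw index, ties counted as 0.5.
#' @export
setClass("PpRmseResult",
  representation(rmseFull = "numeric", rmseNull = "numeric",
                 ppFullBetter = "numeric"))

setValidity("PpRmseResult", function(object) {
  if (any(object@rmseFull < 0) || any(object@rmseNull < 0))
    return("RMSE draws must be non-negative")
  if (object@ppFullBetter < 0 || object@ppFullBetter > 1)
    return("ppFullBetter must be in [0, 1]")
  TRUE
})

#' SimulatedStudy: synthetic rearing-study data with known truth
#'
#' @slot otu the simulated [OtuExperiment] (metadata in `colData`).
#' @slot caterpillars per-caterpillar design and survival table (one row per
#'   reared caterpillar, including those that died before sampling).
#' @slot truth list of all generative parameters and realized quantities.
#' @export
setClass("SimulatedStudy",
  representation(otu = "OtuExperiment", caterpillars = "data.frame",
                 truth = "list"))

#' ClassificationResult: random-forest classification of samples
#'
#' @slot task label that was classified.
#' @slot confusion confusion matrix (rows = true classes).
#' @slot oobAccuracy out-of-bag accuracy.
#' @slot importance data.frame of OTUs ranked by mean decrease in GINI.
#' @export
setClass("ClassificationResult",
  representation(task = "character", confusion = "matrix",
                 oobAccuracy = "numeric", importance = "data.frame"))
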