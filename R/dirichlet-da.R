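#' Multinomial-Dirichlet relative-abundance model per treatment group
#'
#' Counts within a group are modelled as multinomial draws with a shared
#' true relative-abundance vector pi, with a symmetric Dirichlet(alpha0, ...,
#' alpha0) prior (alpha0 = 1 by default, i.e. uniform). The posterior is
#' conjugate - Dirichlet(alpha0 + within-group column sums) - and is sampled
#' directly (no MCMC) via normalized gamma variates. Each group's draw stream
#' is keyed by (seed, group label), so permuting sample order leaves all
#' results unchanged.
#'
#' @param x an [OtuExperiment-class] (typically rarefied to a common depth)
#'   or a samples x OTUs count matrix.
#' @param groups per-sample group labels; every group needs >= 2 samples
#'   (single-sample groups give no valid basis for inference and are
#'   rejected).
#' @param alpha0 prior concentration per OTU (default 1).
#' @param nDraws posterior draws per group (default 10000).
#' @param seed integer seed.
#' @return a [DaFit-class].
#' @export
fitDirichletMultinomial <- function(x, groups, alpha0 = 1, nDraws = 10000,
                                    seed = 1L) {
  m <- daCountMatrix(x)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m), alpha0 > 0, nDraws >= 1)
  tab <- table(groups)
  if (any(tab < 2))
    stop("group(s) with a single sample (minimum n = 2 for valid inference): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  glev <- sort(unique(groups))
  K <- ncol(m)
  alphaPost <- matrix(NA_real_, length(glev), K,
                      dimnames = list(glev, colnames(m)))
  for (g in glev)
    alphaPost[g, ] <- alpha0 + colSums(m[groups == g, , drop = FALSE])
  piDraws <- lapply(glev, function(g)
    withSeed(stringSeed(seed, g), rdirichlet(nDraws, alphaPost[g, ])))
  names(piDraws) <- glev
  sm <- do.call(rbind, lapply(glev, function(g) {
    qs <- apply(piDraws[[g]], 2, stats::quantile,
                probs = c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(group = g, otu = colnames(m), pm = qs[1, ], lower = qs[2, ],
               upper = qs[3, ], row.names = NULL)
  }))
  new("DaFit", groups = glev, alphaPost = alphaPost, piDraws = piDraws,
      summary = sm, alpha0 = alpha0)
}

daCountMatrix <- function(x) {
  m <- if (is(x, "OtuExperiment")) t(counts(x)) else as.matrix(x)
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("otu%03d", seq_len(ncol(m)))
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  m
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Per-OTU, per-group-pair posterior difference probabilities
#'
#' For each OTU and each ordered pair of groups (A, B), the fraction of
#' paired posterior draws with pi_A > pi_B. OTUs whose maximum pairwise
#' probability reaches `threshold` (default 0.99) are flagged as
#' differentially abundant.
#'
#' @param fit a [DaFit-class] with >= 2 groups.
#' @param threshold flagging threshold on the pairwise posterior probability.
#' @return data.frame with columns otu, group_a, group_b, pp and a logical
#'   `flagged` column (max pairwise pp over the OTU >= threshold).
#' @export
otuDifferenceProbs <- function(fit, threshold = 0.99) {
  if (length(fit@groups) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(fit@groups, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ppAB <- colMeans(fit@piDraws[[a]] > fit@piDraws[[b]])
    otus <- colnames(fit@alphaPost)
    rows[[length(rows) + 1]] <- data.frame(
      otu = rep(otus, 2), group_a = rep(c(a, b), each = length(otus)),
      group_b = rep(c(b, a), each = length(otus)),
      pp = c(ppAB, 1 - ppAB), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  mx <- tapply(out$pp, out$otu, max)
  # a Monte-Carlo pp of 1 reflects finite draws, not certainty, so a
  # threshold of 1 (or more) can never be met
  out$flagged <- if (threshold >= 1) rep(FALSE, nrow(out))
  else as.vector(mx[out$otu] >= threshold)
  out
}

#' Posterior-predictive RMSE comparison of group-specific vs pooled models
#'
#' Fits the multinomial-Dirichlet model twice: once allowing a separate true
#' relative-abundance vector per group (full) and once constraining all
#' samples to share one vector (null). For each posterior draw of each model,
#' predicted counts for every sample are simulated from a multinomial
#' conditioned on that sample's observed total, and the root-mean-square
#' error over all sample x OTU cells against the observed counts is recorded.
#' The models are contrasted by pairing draws by index:
#' `ppFullBetter = Pr(RMSE_full < RMSE_null)`, ties counted as 0.5.
#'
#' @inheritParams fitDirichletMultinomial
#' @return a [PpRmseResult-class].
#' @export
ppRmseCompare <- function(x, groups, alpha0 = 1, nDraws = 10000, seed = 1L) {
  m <- daCountMatrix(x)
  groups <- as.character(groups)
  full <- fitDirichletMultinomial(m, groups, alpha0, nDraws,
                                  seed = stringSeed(seed, "full"))
  null <- fitDirichletMultinomial(m, rep("all", nrow(m)), alpha0, nDraws,
                                  seed = stringSeed(seed, "null"))
  rmseFull <- withSeed(stringSeed(seed, "pp-full"),
                       ppRmseDraws(m, groups, full))
  rmseNull <- withSeed(stringSeed(seed, "pp-null"),
                       ppRmseDraws(m, rep("all", nrow(m)), null))
  pp <- mean((rmseFull < rmseNull) + 0.5 * (rmseFull == rmseNull))
  new("PpRmseResult", rmseFull = rmseFull, rmseNull = rmseNull,
      ppFullBetter = pp)
}

# Per-draw posterior-predictive RMSE over all sample x OTU cells, with
# predicted counts conditioned on each sample's observed total.
ppRmseDraws <- function(m, groups, fit) {
  nDraws <- nrow(fit@piDraws[[1]])
  totals <- rowSums(m)
  sq <- numeric(nDraws)
  nCells <- length(m)
  for (s in seq_len(nrow(m))) {
    pd <- fit@piDraws[[groups[s]]]
    obs <- m[s, ]
    tot <- totals[s]
    for (j in seq_len(nDraws)) {
      pred <- stats::rmultinom(1, tot, pd[j, ])[, 1]
      sq[j] <- sq[j] + sum((obs - pred)^2)
    }
  }
  sqrt(sq / nCells)
}

setMethod("show", "DaFit", function(object) {
  cat("Multinomial-Dirichlet fit:", length(object@groups), "group(s),",
      ncol(object@alphaPost), "OTUs,", nrow(object@piDraws[[1]]),
      "posterior draws\n")
})

setMethod("show", "PpRmseResult", function(object) {
  cat(sprintf(
    "PP-RMSE comparison: full %.3f vs null %.3f (posterior medians); ",
    stats::median(object@rmseFull), stats::median(object@rmseNull)))
  cat(sprintf("Pr(full better) = %.3f\n", object@ppFullBetter))
})
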