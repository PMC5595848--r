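#' Bayesian group model with unequal variances
#'
#' A Bayesian analogue of one-way ANOVA without the equal-variance
#' constraint: each group's values are Normal(mu_g, 1/tau_g) with independent
#' Normal(coefMean, 1/coefPrecision) priors on the means and
#' gamma(precisionShape, precisionRate) priors on the precisions. Sampled by
#' Gibbs from the exact conjugate conditionals:
#' mu_g | tau_g ~ Normal((tau0*m0 + tau_g*sum y) / (tau0 + n*tau_g),
#' 1/(tau0 + n*tau_g)) and tau_g | mu_g ~ Gamma(shape + n/2,
#' rate + sum(y - mu_g)^2 / 2). Group standard deviations are reported as
#' sigma_g = 1/sqrt(tau_g).
#'
#' @param values numeric response per sample.
#' @param groups group label per sample; every group needs >= 1 observation.
#' @param prior a [priorSpec()].
#' @param settings an [mcmcSettings()].
#' @param fixedPrecision if non-NULL, the residual precision of every group
#'   is fixed at this value instead of being sampled (used for closed-form
#'   validation).
#' @return a [GroupModelFit-class].
#' @export
fitGroupModel <- function(values, groups, prior = priorSpec(),
                          settings = mcmcSettings(), fixedPrecision = NULL) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  glev <- unique(groups)
  ylist <- split(values, factor(groups, levels = glev))
  if (any(vapply(ylist, length, 0L) == 0)) stop("empty group")
  params <- c(paste0("mu_", glev), paste0("sigma_", glev))
  tau0 <- prior@coefPrecision
  m0 <- prior@coefMean
  nKeep <- floor(settings@nIter / settings@thin)

  runChain <- function(chainSeed) {
    withSeed(chainSeed, {
      mu <- vapply(ylist, mean, 0)
      tau <- vapply(ylist, function(y)
        if (length(y) > 1 && stats::var(y) > 0) 1 / stats::var(y) else 1, 0)
      if (!is.null(fixedPrecision)) tau[] <- fixedPrecision
      draws <- matrix(NA_real_, nKeep, length(params))
      ll <- numeric(nKeep)
      keep <- 0L
      total <- settings@burnIn + settings@nIter
      for (t in seq_len(total)) {
        for (g in seq_along(ylist)) {
          y <- ylist[[g]]
          n <- length(y)
          prec <- tau0 + n * tau[g]
          mu[g] <- stats::rnorm(1, (tau0 * m0 + tau[g] * sum(y)) / prec,
                                sqrt(1 / prec))
          if (is.null(fixedPrecision))
            tau[g] <- stats::rgamma(1, prior@precisionShape + n / 2,
                                    prior@precisionRate +
                                      sum((y - mu[g])^2) / 2)
        }
        it <- t - settings@burnIn
        if (it > 0 && it %% settings@thin == 0 && keep < nKeep) {
          keep <- keep + 1L
          draws[keep, ] <- c(mu, 1 / sqrt(tau))
          ll[keep] <- groupLogLik(ylist, mu, 1 / sqrt(tau))
        }
      }
      list(draws = draws[seq_len(keep), , drop = FALSE],
           ll = ll[seq_len(keep)])
    })
  }

  res <- lapply(seq_len(settings@nChains), function(ch)
    runChain(settings@seed + ch))
  llFun <- function(theta) {
    groupLogLik(ylist, theta[paste0("mu_", glev)],
                theta[paste0("sigma_", glev)])
  }
  cs <- chainSet(lapply(res, `[[`, "draws"), params,
                 logLik = lapply(res, `[[`, "ll"), logLikFun = llFun)
  sm <- summarizePosterior(cs)
  sm$group <- rep(glev, 2)
  new("GroupModelFit", groups = glev, summary = sm, chains = cs)
}

groupLogLik <- function(ylist, mu, sigma) {
  s <- 0
  for (g in seq_along(ylist))
    s <- s + sum(stats::dnorm(ylist[[g]], mu[g], sigma[g], log = TRUE))
  s
}

#' Posterior probability of a contrast between two group means
#'
#' Computed from paired pooled draws within the joint fit: the fraction of
#' draws with mu_a > mu_b.
#'
#' @param fit a [GroupModelFit-class].
#' @param a,b group labels to contrast.
#' @return probability in \[0, 1\].
#' @export
contrastProbability <- function(fit, a, b) {
  d <- pooledDraws(fit@chains)
  mean(d[, paste0("mu_", a)] > d[, paste0("mu_", b)])
}

# Build the model matrix: intercept + supplied covariates; error on rank
# deficiency, naming the offending columns.
buildDesign <- function(design) {
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Bayesian linear regression via Gibbs sampling
#'
#' y ~ Normal(X beta, 1/tau) with independent Normal(coefMean,
#' 1/coefPrecision) priors on all coefficients (intercept included) and a
#' gamma(precisionShape, precisionRate) prior on tau. The full conditional
#' for beta is multivariate normal and for tau gamma; per-draw
#' log-likelihoods are recorded and DIC computed (deviance at the posterior
#' means of beta and tau).
#'
#' @param y numeric response.
#' @param design data.frame or matrix of covariates *without* intercept;
#'   binary covariates coded 0/1, age in raw days.
#' @param prior a [priorSpec()].
#' @param settings an [mcmcSettings()].
#' @param fixedPrecision optional fixed residual precision (no tau updates).
#' @return a [RegressionFit-class]; coefficients include the residual
#'   standard deviation as row `sigma`.
#' @export
fitLinearModel <- function(y, design, prior = priorSpec(),
                           settings = mcmcSettings(),
                           fixedPrecision = NULL) {
  X <- buildDesign(design)
  stopifnot(length(y) == nrow(X))
  p <- ncol(X)
  n <- length(y)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  tau0 <- prior@coefPrecision
  m0 <- rep(prior@coefMean, p)
  nKeep <- floor(settings@nIter / settings@thin)
  params <- c(colnames(X), "sigma")

  runChain <- function(chainSeed) {
    withSeed(chainSeed, {
      v <- stats::var(y)
      if (!is.finite(v) || v <= 0) v <- 1
      tau <- fixedPrecision %||% (1 / v)
      beta <- rep(0, p)
      draws <- matrix(NA_real_, nKeep, p + 1)
      ll <- numeric(nKeep)
      keep <- 0L
      for (t in seq_len(settings@burnIn + settings@nIter)) {
        prec <- tau * XtX + diag(tau0, p)
        ch <- chol(prec)
        mean_b <- backsolve(ch, forwardsolve(t(ch), tau * Xty + tau0 * m0))
        beta <- mean_b + backsolve(ch, stats::rnorm(p))
        if (is.null(fixedPrecision)) {
          resid <- y - X %*% beta
          tau <- stats::rgamma(1, prior@precisionShape + n / 2,
                               prior@precisionRate + sum(resid^2) / 2)
        }
        it <- t - settings@burnIn
        if (it > 0 && it %% settings@thin == 0 && keep < nKeep) {
          keep <- keep + 1L
          draws[keep, ] <- c(beta, 1 / sqrt(tau))
          ll[keep] <- sum(stats::dnorm(y, X %*% beta, 1 / sqrt(tau),
                                       log = TRUE))
        }
      }
      list(draws = draws[seq_len(keep), , drop = FALSE],
           ll = ll[seq_len(keep)])
    })
  }

  res <- lapply(seq_len(settings@nChains), function(ch)
    runChain(settings@seed + ch))
  llFun <- function(theta)
    sum(stats::dnorm(y, X %*% theta[colnames(X)], theta["sigma"], log = TRUE))
  cs <- chainSet(lapply(res, `[[`, "draws"), params,
                 logLik = lapply(res, `[[`, "ll"), logLikFun = llFun)
  new("RegressionFit", coefficients = summarizePosterior(cs),
      dic = mcmcDic(cs), chains = cs, family = "gaussian", design = X)
}

#' Bayesian logistic regression via adaptive Metropolis
#'
#' Bernoulli likelihood with logit link and Normal(coefMean,
#' 1/coefPrecision) priors on the coefficients. Sampled with a joint
#' random-walk Metropolis proposal whose scale adapts towards a 0.2-0.4
#' acceptance rate during burn-in only (adaptation is frozen afterwards to
#' preserve detailed balance). Complete separation or a constant response
#' does not fail - the prior is proper - but emits a diagnostic warning.
#'
#' @inheritParams fitLinearModel
#' @param y logical or 0/1 response.
#' @return a [RegressionFit-class].
#' @export
fitLogisticModel <- function(y, design, prior = priorSpec(),
                             settings = mcmcSettings()) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  X <- buildDesign(design)
  p <- ncol(X)
  if (all(y == 1) || all(y == 0))
    warning("constant response: posterior driven by the prior tails")
  else {
    mle <- suppressWarnings(stats::glm.fit(X, y,
                                           family = stats::binomial()))
    if (any(abs(mle$coefficients) > 15, na.rm = TRUE))
      warning("possible complete separation: coefficient posteriors may be ",
              "prior-dominated in one tail")
  }
  tau0 <- prior@coefPrecision
  m0 <- prior@coefMean
  logPost <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))) -
      0.5 * tau0 * sum((beta - m0)^2)
  }
  logLik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  nKeep <- floor(settings@nIter / settings@thin)

  runChain <- function(chainSeed) {
    withSeed(chainSeed, {
      beta <- rep(0, p)
      lp <- logPost(beta)
      step <- 2.4 / sqrt(p)
      acc <- 0L
      win <- 0L
      draws <- matrix(NA_real_, nKeep, p)
      ll <- numeric(nKeep)
      keep <- 0L
      for (t in seq_len(settings@burnIn + settings@nIter)) {
        prop <- beta + stats::rnorm(p, 0, step)
        lpProp <- logPost(prop)
        if (log(stats::runif(1)) < lpProp - lp) {
          beta <- prop
          lp <- lpProp
          acc <- acc + 1L
        }
        win <- win + 1L
        if (t <= settings@burnIn && win == 50L) {
          rate <- acc / win
          if (rate < 0.2) step <- step * 0.8
          else if (rate > 0.4) step <- step * 1.25
          acc <- 0L; win <- 0L
        }
        it <- t - settings@burnIn
        if (it > 0 && it %% settings@thin == 0 && keep < nKeep) {
          keep <- keep + 1L
          draws[keep, ] <- beta
          ll[keep] <- logLik(beta)
        }
      }
      list(draws = draws[seq_len(keep), , drop = FALSE],
           ll = ll[seq_len(keep)])
    })
  }

  res <- lapply(seq_len(settings@nChains), function(ch)
    runChain(settings@seed + ch))
  llFun <- function(theta) logLik(theta[colnames(X)])
  cs <- chainSet(lapply(res, `[[`, "draws"), colnames(X),
                 logLik = lapply(res, `[[`, "ll"), logLikFun = llFun)
  new("RegressionFit", coefficients = summarizePosterior(cs),
      dic = mcmcDic(cs), chains = cs, family = "binomial", design = X)
}

#' Fitted probabilities for covariate combinations (logistic fits)
#'
#' Posterior summaries of `plogis(x' beta)` for each row of `newdata`, e.g.
#' fitted survival probabilities per population x plant cell.
#'
#' @param fit a binomial [RegressionFit-class].
#' @param newdata data.frame of covariates matching the fit's design
#'   (without intercept).
#' @return data.frame: one row per `newdata` row with pm and 95% ETPI.
#' @export
fittedProbabilities <- function(fit, newdata) {
  stopifnot(fit@family == "binomial")
  X <- cbind(1, as.matrix(newdata))
  d <- pooledDraws(fit@chains)
  out <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
    pr <- stats::plogis(d %*% X[i, ])
    qs <- stats::quantile(pr, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(pm = qs[1], lower = qs[2], upper = qs[3])
  }))
  cbind(newdata, out)
}

setMethod("show", "GroupModelFit", function(object) {
  cat("Bayesian group model (unequal variances),",
      length(object@groups), "groups\n")
  print(object@summary, digits = 3)
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("Bayesian %s regression\n", object@family))
  print(object@coefficients, digits = 3)
  cat(sprintf("DIC = %.2f (pD = %.2f)\n", object@dic["DIC"],
              object@dic["pD"]))
})
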