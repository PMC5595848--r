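test_that("group-model Gibbs matches the conjugate closed form (fixed tau)", {
  # tau fixed at 1, y = {1,2,3}: mu | y ~ Normal(6/(3 + 1e-6), 1/(3 + 1e-6))
  f <- fitGroupModel(c(1, 2, 3), rep("g", 3), fixedPrecision = 1,
                     settings = fastSettings(seed = 5, nIter = 4000, thin = 1))
  d <- larvalGut:::pooledDraws(f@chains)[, "mu_g"]
  postMean <- 6 / (3 + 1e-6)
  postSd <- sqrt(1 / (3 + 1e-6))
  # with fixed tau the Gibbs draws are iid from the exact posterior
  mcse <- postSd / sqrt(length(d))
  expect_lt(abs(mean(d) - postMean), 3 * mcse)
  expect_lt(abs(mean(d) - 2), 3 * mcse + 1e-5)
  expect_equal(sd(d), postSd, tolerance = 0.05)
})

test_that("group contrasts behave under symmetry and strong separation", {
  set.seed(2)
  y <- rnorm(40)
  f <- fitGroupModel(c(y, y), rep(c("A", "B"), each = 40),
                     settings = fastSettings(seed = 1))
  expect_lt(abs(contrastProbability(f, "A", "B") - 0.5), 0.06)
  sm <- f@summary
  expect_lt(abs(sm$pm[sm$parameter == "mu_A"] -
                  sm$pm[sm$parameter == "mu_B"]), 0.05)
  # means 10 sd apart at n = 50: essentially certain ordering
  y2 <- c(rnorm(50, 10, 1), rnorm(50, 0, 1))
  f2 <- fitGroupModel(y2, rep(c("hi", "lo"), each = 50),
                      settings = fastSettings(seed = 2))
  expect_gt(contrastProbability(f2, "hi", "lo"), 0.99)
  expect_error(fitGroupModel(numeric(0), character(0)))
})

test_that("linear model concentrates on a noiseless target and rejects collinearity", {
  x <- seq_len(50)
  fit <- fitLinearModel(2 + 3 * x, data.frame(x = x),
                        settings = fastSettings(seed = 3))
  co <- fit@coefficients
  expect_equal(co$pm[co$parameter == "(Intercept)"], 2, tolerance = 0.05)
  expect_equal(co$pm[co$parameter == "x"], 3, tolerance = 0.01)
  expect_true(co$lower[co$parameter == "x"] <= 3 &&
                co$upper[co$parameter == "x"] >= 3)
  expect_error(fitLinearModel(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "collinear.*b")
})

test_that("linear-model Gibbs matches the analytic normal posterior at fixed tau", {
  set.seed(4)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n)
  tau <- 1; tau0 <- 1e-6
  prec <- tau * crossprod(X) + diag(tau0, 3)
  postMean <- solve(prec, tau * crossprod(X, y))
  postCov <- solve(prec)
  fit <- fitLinearModel(y, data.frame(x1 = X[, 2], x2 = X[, 3]),
                        fixedPrecision = tau,
                        settings = fastSettings(seed = 6, nIter = 4000,
                                                thin = 1))
  d <- larvalGut:::pooledDraws(fit@chains)[, 1:3]
  mcse <- sqrt(diag(postCov)) / sqrt(nrow(d)) # draws iid given fixed tau
  expect_true(all(abs(colMeans(d) - drop(postMean)) < 3 * mcse))
  expect_equal(unname(cov(d)), unname(postCov), tolerance = 0.1)
})

test_that("pinning the coefficient prior recovers the limiting model", {
  # coefficient precision -> infinity forces beta towards the prior mean 0,
  # so predictions collapse to the intercept-free prior mean
  set.seed(8)
  x <- rnorm(40)
  y <- 1 + 2 * x + rnorm(40, 0, 0.5)
  fit <- fitLinearModel(y, data.frame(x = x),
                        prior = priorSpec(coefPrecision = 1e10),
                        settings = fastSettings(seed = 9))
  expect_lt(abs(fit@coefficients$pm[2]), 1e-3)
})

test_that("logistic sampler is symmetric, recovers truth, flags degeneracy", {
  # intercept-only, 5 successes / 5 failures
  f <- fitLogisticModel(rep(c(TRUE, FALSE), 5),
                        data.frame()[1:10, , drop = FALSE],
                        settings = fastSettings(seed = 1, nIter = 4000))
  expect_lt(abs(f@coefficients$pm[1]), 0.25)
  # recovery at moderate n
  set.seed(12)
  n <- 800
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  beta <- c(-0.5, -0.56, -0.15)
  pr <- plogis(beta[1] + beta[2] * x1 + beta[3] * x2)
  y <- runif(n) < pr
  fit <- fitLogisticModel(y, data.frame(pop = x1, plant = x2),
                          settings = fastSettings(seed = 2, nIter = 6000))
  co <- fit@coefficients
  postSd <- (co$upper - co$lower) / (2 * 1.96)
  expect_true(all(abs(co$pm - beta) < 3 * postSd))
  # constant response warns but does not fail
  expect_warning(
    fit1 <- fitLogisticModel(rep(TRUE, 10), data.frame()[1:10, , drop = FALSE],
                             settings = fastSettings(seed = 3)),
    "constant response")
  expect_gt(fit1@coefficients$pm[1], 1.5)
})

test_that("fitted probabilities summarize plogis(X beta) draws", {
  set.seed(5)
  y <- rbinom(100, 1, 0.3)
  fit <- fitLogisticModel(y, data.frame()[1:100, , drop = FALSE],
                          settings = fastSettings(seed = 4))
  pr <- fittedProbabilities(fit, data.frame()[1, , drop = FALSE])
  expect_equal(pr$pm, mean(y), tolerance = 0.1)
  expect_true(pr$lower < pr$pm && pr$pm < pr$upper)
})

test_that("posterior summaries report pm, ETPI and tail probabilities", {
  cs <- larvalGut:::chainSet(list(matrix(c(1, 2, 3, 4, 5), ncol = 1)), "a")
  sm <- summarizePosterior(cs)
  expect_equal(sm$pm, 3)
  set.seed(6)
  big <- matrix(rnorm(1e6), ncol = 1)
  colnames(big) <- "z"
  smb <- summarizePosterior(big)
  expect_equal(smb$lower, -1.96, tolerance = 0.01)
  expect_equal(smb$upper, 1.96, tolerance = 0.01)
  expect_equal(smb$pp_gt0, 0.5, tolerance = 0.01)
  expect_equal(smb$pp_gt0 + smb$pp_lt0, 1) # no draws exactly 0
  expect_true(smb$lower <= smb$pm && smb$pm <= smb$upper)
})

test_that("Gelman-Rubin diagnoses convergence and divergence", {
  set.seed(7)
  m <- matrix(rnorm(5000), ncol = 1)
  same <- larvalGut:::chainSet(list(m, m), "a")
  expect_equal(unname(gelmanRubin(same)), 1) # identical chains floor at 1
  iid <- larvalGut:::chainSet(
    lapply(1:3, function(i) matrix(rnorm(5000), ncol = 1)), "a")
  expect_lt(gelmanRubin(iid), 1.01)
  apart <- larvalGut:::chainSet(
    list(matrix(rnorm(500), ncol = 1), matrix(rnorm(500, 10), ncol = 1)), "a")
  expect_gt(gelmanRubin(apart), 1.1)
  expect_error(gelmanRubin(larvalGut:::chainSet(list(m), "a")), ">= 2 chains")
})

test_that("effective sample size tracks the AR(1) closed form", {
  set.seed(8)
  iid <- larvalGut:::chainSet(list(matrix(rnorm(5000), ncol = 1)), "a")
  expect_gt(effectiveSampleSize(iid), 0.9 * 5000)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 4000))
  essAr <- effectiveSampleSize(
    larvalGut:::chainSet(list(matrix(ar, ncol = 1)), "a"))
  theory <- 4000 * (1 - 0.9) / (1 + 0.9)
  expect_gt(essAr, theory / 1.5)
  expect_lt(essAr, theory * 1.5)
  expect_warning(
    ess0 <- effectiveSampleSize(
      larvalGut:::chainSet(list(matrix(1, 100, 1)), "a")),
    "constant chain")
  expect_equal(unname(ess0), 0)
})

test_that("DIC: degenerate chains have pD = 0 and a fixed-mean model pD ~ 1", {
  oneDraw <- matrix(rep(c(0.5, 1), each = 50), 50, 2)
  cs <- larvalGut:::chainSet(list(oneDraw), c("mu", "sigma"),
                             logLik = list(rep(-10, 50)),
                             logLikFun = function(th) -10)
  d <- mcmcDic(cs)
  expect_equal(unname(d["pD"]), 0)
  expect_equal(unname(d["DIC"]), unname(d["Dbar"]))
  # normal-mean model with fixed precision: one effective parameter
  set.seed(9)
  pds <- vapply(1:10, function(i) {
    y <- rnorm(100)
    fit <- fitLinearModel(y, data.frame()[1:100, , drop = FALSE],
                          fixedPrecision = 1,
                          settings = fastSettings(seed = i, nChains = 1L))
    fit@dic[["pD"]]
  }, 0)
  expect_lt(abs(mean(pds) - 1), 0.3)
  expect_error(mcmcDic(larvalGut:::chainSet(list(oneDraw), c("a", "b"))),
               "no log-likelihood")
})

test_that("chain bookkeeping: thinning count, determinism, TSV export", {
  st <- mcmcSettings(nChains = 2, burnIn = 100, nIter = 1000, thin = 3,
                     seed = 42)
  f1 <- fitLinearModel(rnorm(20), data.frame(x = rnorm(20)), settings = st)
  expect_equal(nrow(f1@chains@draws[[1]]), floor(1000 / 3))
  f2 <- fitLinearModel(rnorm(20), data.frame(x = rnorm(20)), settings = st)
  # determinism: same seed settings, same data => identical draws
  y <- rnorm(20); x <- data.frame(x = rnorm(20))
  expect_identical(fitLinearModel(y, x, settings = st)@chains@draws,
                   fitLinearModel(y, x, settings = st)@chains@draws)
  path <- tempfile(fileext = ".tsv")
  writeChains(f1@chains, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 2 * 333 * length(f1@chains@paramNames))
  expect_setequal(unique(tab$parameter), f1@chains@paramNames)
})
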