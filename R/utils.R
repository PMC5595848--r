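# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded subroutines do not perturb each other.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-adic string hash folded into [0, 2^31 - 2]; used to derive
# one independent RNG stream per (seed, label) pair so that e.g. dropping a
# sample does not shift the rarefaction draws of the others.
stringSeed <- function(seed, label) {
  m <- 2147483647
  acc <- 7
  for (code in utf8ToInt(as.character(label)))
    acc <- (acc * 31 + code) %% m
  as.integer((acc + as.numeric(seed)) %% m)
}

# Quantile-based posterior summary of a draw vector.
drawSummary <- function(draws) {
  qs <- stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE)
  data.frame(pm = qs[1], lower = qs[2], upper = qs[3],
             pp_gt0 = mean(draws > 0), pp_lt0 = mean(draws < 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
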