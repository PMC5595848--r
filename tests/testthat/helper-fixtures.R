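# Shared fixtures and reduced-size settings for the test suite.

# Small OTU table: counts are OTUs x samples.
makeOtu <- function(counts, taxonomy = NULL, sampleData = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("otu%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(taxonomy))
    taxonomy <- sprintf("k__Bacteria; p__Firmicutes; c__Bacilli; o__o%d; g__g%d",
                        seq_len(nrow(counts)), seq_len(nrow(counts)))
  OtuExperiment(counts, taxonomy, sampleData)
}

# A 4-OTU x 3-sample TSV fixture on disk; returns the path.
writeTsvFixture <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    "otu_id\tsampleA\tsampleB\tsampleC\ttaxonomy",
    "otu1\t5\t0\t2\tk__Bacteria; p__Proteobacteria; g__Pseudomonas",
    "otu2\t3\t7\t1\tk__Bacteria; p__Firmicutes; o__Lactobacillales",
    "otu3\t0\t1\t9\tk__Bacteria; p__Cyanobacteria; c__Chloroplast",
    "otu4\t2\t2\t2\tUnassigned")
  writeLines(lines, path)
  path
}

# Short MCMC schedule for unit tests; still multi-chain and thinned.
fastSettings <- function(seed = 1L, nChains = 2L, burnIn = 200L,
                         nIter = 1200L, thin = 2L)
  mcmcSettings(nChains = nChains, burnIn = burnIn, nIter = nIter,
               thin = thin, seed = seed)

# Small synthetic-study configuration: the full design but fewer OTUs so the
# multinomial draws are cheap. Generative coefficients keep their defaults.
smallSimConfig <- function(seed = 1L, ...)
  simulationConfig(nOtus = 16L, plantReps = 2L, seed = seed, ...)

# Brute-force UPGMA oracle: recompute all average inter-cluster distances
# from the raw matrix at every step. Returns merge heights (dissimilarity
# scale) and member sets at each merge, ties broken by lowest pair index.
bruteUpgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < bestD - 1e-12) { bestD <- avg; best <- c(i, j) }
    }
    heights <- c(heights, bestD)
    members[[length(members) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, members = members)
}

# Numerical oracle for P(X > Y) with X ~ Beta(a1, b1), Y ~ Beta(a2, b2).
betaGreaterProb <- function(a1, b1, a2, b2) {
  stats::integrate(function(x)
    stats::dbeta(x, a1, b1) * stats::pbeta(x, a2, b2),
    0, 1, rel.tol = 1e-9)$value
}
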