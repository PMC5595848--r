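# larvalGut

Bayesian analysis of caterpillar gut microbiome variation from 16S OTU
tables.

## The problem

Rearing experiments that track caterpillar gut communities sample three
things: **frass** (a non-lethal proxy for the gut), **whole caterpillars**
(lethal, enriched for intracellular symbionts such as *Wolbachia*), and the
**host plants** (leaf epiphytes and endophytes). The questions are whether
gut communities differ by sample type, host plant, source population and
larval age; whether individual microbes shift in relative abundance across
population × plant treatments; and whether the microbiome predicts larval
performance (weight, survival). `larvalGut` implements the full downstream
analysis for this design — everything after OTU picking — for microbial
ecologists working with Greengenes-style OTU tables.

## What it computes

* **OTU-table handling** — an `OtuExperiment` container (a
  `SummarizedExperiment`), TSV/BIOM-JSON readers, taxonomy filters
  (chloroplast, mitochondria, *Wolbachia*, unassigned, rare OTUs) and seeded
  rarefaction by multivariate hypergeometric subsampling.
* **Community structure** — chord-transformed PCA, Bray-Curtis PCoA, Hill
  diversity `qD = (Σ p_i^q)^(1/(1−q))` at `q = 2` (the effective number of
  phylotypes), and UPGMA clustering with newick export.
* **Bayesian models**, sampled by Gibbs/Metropolis samplers written from
  their full conditionals with diffuse priors (Normal(0, τ = 1e−6) on
  coefficients, gamma(0.01, 0.01) on precisions): an unequal-variance group
  model (a Bayesian one-way ANOVA analogue), linear models for community
  metrics and weight, a Bernoulli-logit survival model, posterior medians
  (pm), 95% equal-tail intervals (ETPIs), tail posterior probabilities (pp),
  Gelman–Rubin and effective-sample-size diagnostics, and DIC with
  Spiegelhalter's pD.
* **Differential relative abundance** — conjugate multinomial-Dirichlet
  models per treatment group (π ~ Dirichlet(1, …, 1), sampled directly),
  per-OTU pairwise posterior difference probabilities, and a
  posterior-predictive RMSE comparison of the group-specific model against a
  pooled null: `pp = Pr(RMSE_full < RMSE_null)` over paired draws.
* **Classification** — 50,000-tree random forests with mean-decrease-GINI
  importances, for sample type / plant / population / age.
* **Synthetic data** — `simulateStudy()` generates the whole design (181
  caterpillars, 2 populations × 2 host plants × 3 ages × 3 sample types,
  Dirichlet-multinomial counts, a *Wolbachia* spike in whole-caterpillar
  samples, an age-driven diversity decline, amplification failures) with
  every generating parameter recorded, so estimator recovery is testable.

## Worked example

```r
library(larvalGut)

study  <- simulateStudy(simulationConfig(seed = 1))
config <- pipelineConfig(rfTrees = 1000L, daDraws = 2000L,
                         settings = mcmcSettings(nChains = 2, burnIn = 500,
                                                 nIter = 3000, thin = 3))
report <- runPipeline(study, config)
```

The study prints as

```
SimulatedStudy: 181 caterpillars, 150 samples

          frass           larva plant_endophyte  plant_epiphyte
            109              29               6               6
```

and the report holds, among others (output of this exact run):

```
survival to 15 d: 0.30
survival beta_pop pm = -0.45 [-1.09, 0.23]
diversity beta_age pm = -0.175 [-0.204, -0.146]
PC1+PC2 variance explained: 93%
PP-RMSE pp(full better) = 1.000 over 72 frass samples
stage-1 RF OOB accuracy = 0.89, top OTU: wolbachia
weight beta_plant pm = -0.95, beta_age pm = 0.19; best DIC model: PC1
```

Reading this: about 30% of caterpillars survived to day 15, with the BST
population at lower odds (pm −0.45, ETPI still crossing 0 at n = 181);
effective phylotype diversity drops by ~0.18 per day of larval age; the
treatment-specific relative-abundance model beats the pooled null in every
paired posterior-predictive draw; and sample-type classification is driven by
the *Wolbachia* OTU, which is abundant in whole caterpillars but essentially
absent from frass. Each of these mirrors the generating truth of the
simulation (marginal survival 0.30, diversity slope −0.151 per day,
treatment-dependent compositions, a larva-specific *Wolbachia* spike).

`runPipeline(..., outdir = "out/")` additionally writes `report.json`,
per-analysis TSVs and the UPGMA newick tree. A thin CLI lives at
`inst/scripts/larvalgut-cli.R` (`simulate` and `run` subcommands).

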