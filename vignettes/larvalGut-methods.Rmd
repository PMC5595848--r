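---
title: "Models and methods in larvalGut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in larvalGut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvalGut)
```

# Scope

`larvalGut` analyses 16S OTU count tables from larval rearing experiments in
which caterpillar gut communities are tracked over development through frass
(non-lethal) and whole-caterpillar (lethal) sampling, alongside host-plant
epiphyte/endophyte communities. The package covers everything downstream of
the OTU table: taxonomic filtering, rarefaction, ordination, diversity,
Bayesian models of community metrics and larval performance, differential
relative abundance, classification, and a synthetic-data generator with known
ground truth. Sequence processing (read QC, OTU clustering, taxonomy
assignment) is out of scope; tables are expected in the Greengenes-style TSV
or BIOM-JSON formats produced by standard amplicon pipelines.

# Data model and filtering

An `OtuExperiment` extends `SummarizedExperiment`: OTUs are rows, samples are
columns, the `"counts"` assay holds non-negative integers, `rowData()` the
parsed taxonomy lineage, and `colData()` the design covariates (sample type,
population, host plant, age in days, weight, survival).

Two filter stages mirror the analysis flow of such experiments:

* **Stage 1** removes chloroplast and mitochondrial 16S reads (the V4 primers
  co-amplify both) and unassigned OTUs, then rarefies every sample to a
  common depth (default 1311; samples below the depth are dropped, a sample
  at exactly the depth is kept unchanged).
* **Stage 2** additionally removes plant samples, *Wolbachia* (an
  intracellular endosymbiont that dominates whole-caterpillar samples but is
  not a gut community member) and OTUs that never reach 1% relative abundance
  in any sample, then re-rarefies (default 500). The two rarefactions are
  independent draws from the unrarefied filtered table, not nested
  subsamples.

An OTU is *unassigned* when its lineage is empty, `"Unassigned"`, or carries
no rank below kingdom. *Wolbachia* is matched at the genus rank, falling back
to order Rickettsiales only for genus-less lineages, so that other named
Rickettsiales genera are retained.

**Rarefaction** is a uniform subsample *without replacement* (a multivariate
hypergeometric draw, realized by sequential `rhyper` calls): the procedure
randomly *retains* existing sequences rather than resampling them. Each
sample's draw comes from an independent RNG stream keyed by
`(seed, sample_id)`, so adding or removing samples never perturbs the draws
of the others. With replacement would inflate the variance of rare-OTU
counts; without replacement reproduces subsampling of real reads.

# Ordination, diversity, clustering

* **Chord transform + PCA**: rows are scaled to unit Euclidean norm (chord
  distance), then PCA is run on the column-centered but *not*
  variance-scaled matrix via eigendecomposition of the covariance matrix.
  Each axis is sign-fixed so its largest-magnitude loading is positive —
  eigenvector signs are otherwise arbitrary and platform-dependent. OTU
  loadings are reported for axis interpretation.
* **Bray-Curtis + PCoA**: `vegan::vegdist` distances, classical scaling via
  double-centering of `-D^2/2`. Bray-Curtis is non-Euclidean, so negative
  eigenvalues occur; they are reported, their axes dropped, and the explained
  fractions computed over positive eigenvalues only. No Cailliez/Lingoes
  correction is applied by default — chord-PCA and Bray-Curtis-PCoA axes are
  meant to be directly comparable with the plain classical-scaling results
  this style of analysis reports. On genuinely Euclidean distances, PCoA and
  PCA scores agree axis-by-axis up to sign (tested to 1e-8).
* **Hill diversity**: `qD = (sum p_i^q)^(1/(1-q))`, the effective number of
  equally abundant phylotypes; `q = 2` (inverse Simpson) is the default
  because low orders are unreliable for microbial data. `q = 1` uses the
  entropy limit. Values are bounded by 1 and the observed richness.
* **UPGMA**: size-weighted average linkage (`hclust(method = "average")` is
  exactly classic UPGMA), giving an ultrametric tree with node heights at
  half the average inter-cluster dissimilarity; exported as newick. Ties in
  merge candidates are broken by hclust's deterministic input-order rule
  (a lexicographic tie-break would differ only in the labelling of equal-
  height merges, which the ultrametric output renders immaterial).

# Bayesian models

All models are sampled by samplers written from their full conditionals, so
the package embodies the models rather than delegating to a probabilistic
programming engine. Priors are deliberately diffuse: Normal(0, tau = 1e-6)
on every location/regression coefficient and gamma(0.01, 0.01) on every
precision. The default schedule is 3 chains, a 1000-iteration burn-in, then
10000 iterations with every third draw retained
(`floor(n_iter / thin)` draws per chain). Point estimates are posterior
medians (`pm`), uncertainty 95% equal-tail probability intervals (ETPIs),
and directional evidence the posterior probability (`pp`) that a parameter
or contrast is above/below zero, all computed from pooled post-burn-in
draws.

* **Group model** (`fitGroupModel`): a Bayesian one-way ANOVA analogue
  without the equal-variance constraint — each group has its own Normal mean
  and precision with conjugate Gibbs updates. Used to compare PC/PCO scores
  and diversity across sample types (epiphytes and endophytes are pooled as
  "plant" — their sample sizes are small and their communities overlap).
* **Linear model** (`fitLinearModel`): Gibbs with a multivariate-normal
  conditional for the coefficients and a gamma conditional for the
  precision. Binary covariates are coded 0/1 (larva = 1, Me = 1, BST = 1)
  and age stays in raw days, so slopes are per-day effects; the data do not
  pin these coding choices down, but the reported coefficient signs
  constrain them and this coding reproduces them.
* **Logistic model** (`fitLogisticModel`): Bernoulli likelihood with logit
  link, sampled by joint random-walk Metropolis. The proposal scale adapts
  toward a 0.2-0.4 acceptance rate during burn-in only; adaptation is frozen
  afterwards so the retained chain satisfies detailed balance. The survival
  model codes plant as Lu = 1 (feeding on *L. argenteus* lowers survival)
  and fits main effects only — fitted per-cell survival probabilities are
  derived from the main-effect posterior. Complete separation does not break
  the fit (the prior is proper) but triggers a diagnostic warning.
* **Diagnostics**: classic Gelman-Rubin potential scale reduction (floored
  at 1; identical chains would otherwise report sqrt((n-1)/n)) and effective
  sample size with Geyer's initial-positive pairwise truncation of the
  autocorrelation sum. A constant chain reports ESS 0 with a warning.
* **DIC** uses Spiegelhalter's construction: `Dbar` the posterior mean
  deviance, `pD = Dbar - D(theta_bar)` with the deviance evaluated at the
  posterior means of the sampled parameters, `DIC = Dbar + pD`. Tests
  confirm pD ≈ 1 for a one-parameter model and pD ≈ 0 for a degenerate
  chain.

# Differential relative abundance

Counts within a treatment group (population x host plant) are modelled as
multinomial draws from a shared true relative-abundance vector `pi` with a
uniform Dirichlet(1, ..., 1) prior. The posterior is conjugate —
Dirichlet(alpha0 + within-group count sums) — and sampled directly, no MCMC.
The analysis subset is frass at 15-20 days (minimizing age and sample-type
confounding); groups with fewer than two samples are rejected outright, as a
single sample gives no valid basis for inference. Per-OTU, per-group-pair
posterior probabilities `Pr(pi_A > pi_B)` flag differentially abundant OTUs
at a 0.99 default threshold; a Monte-Carlo pp of exactly 1 reflects finite
draws rather than certainty, so a threshold of 1 can never be met.

**Posterior-predictive RMSE comparison.** The group-specific (full) model is
compared against a pooled (null) model through posterior-predictive counts:
for each draw, every sample's predicted counts are simulated from a
multinomial conditioned on that sample's observed total (so cells are
compared like-for-like), and the RMSE over all sample x OTU cells against
the observed counts is recorded. The two RMSE distributions are contrasted by
pairing draws by index — `Pr(RMSE_full < RMSE_null)` with ties counted as
0.5 — a simple Monte-Carlo estimate that is exact in the limit of draws.
Whether counts are predicted per sample or once per pooled group changes
this comparison (the conjugate update does not); per-sample prediction was
chosen because the observed table is per-sample. All retained OTUs enter the
RMSE by default; a subset option exists for order-level summaries.
Calibration holds by construction and is tested: under exchangeable groups
the pp concentrates near 0.5, and at a total-variation separation of 0.4
(depth 500, 10 samples per group) it exceeds 0.95 in almost every replicate.

# Random forest

`rfClassify` wraps the canonical `randomForest` implementation (GINI splits,
sqrt(K) features per split, out-of-bag evaluation); the full analysis uses
50000 trees and only the tree count is tuned — other hyperparameters keep the
reference defaults. Importance is the mean decrease in GINI. With very few
trees some samples are never out-of-bag and are excluded from the OOB
accuracy.

# Synthetic-data generator

`simulateStudy` emulates the rearing design so every analysis can be
exercised against known truth: 181 caterpillars from 20 maternal families
across two source populations (BST, HWR), host plants (Me = alfalfa,
Lu = *L. argenteus*) assigned in alternation, survival to day 15 from a
Bernoulli-logit model, frass sampled at 15/20/25 days from survivors,
caterpillars sacrificed with per-age probabilities for whole-larva samples,
and replicate plant epiphyte/endophyte samples.

Generating coefficients default to the posterior medians reported for this
design, used here as ground truth for recovery tests: survival
`a0 = -0.49, a_pop = -0.56 (BST), a_plant = -0.15 (Lu)` — the intercept is
the logit of the reported HWR-on-Me survival probability and yields ~30%
marginal survival, matching the observed 31%; weight (mg)
`b0 = 3, b_plant = -0.961 (Me), b_age = 0.225 /day, residual sd 1` (the
intercept and residual sd are not reported and were chosen once to give
realistic mid-instar weights of ~5-10 mg; the unreported population effect
defaults to a modest -0.3); and a diversity decline of -0.151 effective
phylotypes per day.

Compositions are Dirichlet-multinomial: each treatment group has a
concentration vector built from a geometric base composition (ratio 0.75,
total concentration 100, i.e. moderate between-sample compositional noise)
with a few taxonomic orders boosted per plant or population — the kind of
order-level differential abundance the Dirichlet model is meant to detect.
Whole-larva samples mix in a designated *Wolbachia* OTU with a Beta weight
matched to the reported mean 0.37 / s.d. 0.36 (frass carries a trace at mean
7e-4), reproducing the observed pattern without modelling intracellular
biology. Chloroplast, mitochondrial and unassigned OTUs are included at low
concentration in gut samples and dominate plant samples, so both filter
stages do real work. Library sizes are lognormal (meanlog 8.25, sdlog 1);
with probability 0.52 a sample "fails to amplify" and draws a depth below the
stage-1 cutoff — together these reproduce the attrition pattern of such
studies (roughly half of samples failing, ~15% of the rest below the
rarefaction depth).

**Age-dependent diversity.** Rather than applying an uncalibrated power
transform, the generator solves, per age and group, for the exponent `t` on
the concentration vector such that the *expected* inverse-Simpson diversity
of a rarefied sample hits the target line `D15 + slope * (age - 15)`. This
uses the closed form
`E[sum p_hat^2] = (1 - 1/d) * sum a_i(a_i+1) / (A(A+1)) + 1/d`
for counts of depth `d` drawn multinomially from a Dirichlet(a) composition;
`t > 1` sharpens the composition and lowers diversity. Anchoring at
exponent 1 for age 15 makes the generating slope well-defined, and the
fitted per-day slope on simulated data recovers it (the per-sample
`1/sum p_hat^2` estimator is slightly biased upward by Jensen's inequality,
but the bias is nearly age-constant and cancels from the slope).

What the generator does *not* emulate: phylogenetic correlation among OTUs,
maternal (family) random effects, per-sample overdispersion beyond the
Dirichlet-multinomial, contaminant reads, or any feedback of the microbiome
on performance. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to those features of
real data.

# Numerical and design notes

* Every stochastic step is seeded; stage seeds derive from the global seed
  via a deterministic string hash, so dropping one analysis never shifts
  another's draws, and a rerun with the same seed is byte-identical.
* Group labels enter the Dirichlet sampler in sorted order with streams
  keyed by `(seed, group label)`: permuting samples changes nothing;
  renaming a group changes only its Monte-Carlo noise.
* Rank-deficient designs are rejected with the collinear columns named;
  empty groups and all-OTU-removing filters are errors, while zero-count
  samples in the rare-OTU filter only warn (they cast no retention votes).
* Test and example problem sizes are scaled down (hundreds to thousands of
  MCMC draws, 300-1000 trees) — enough for the Monte-Carlo tolerances used;
  the pipeline defaults keep the full schedule (3 x 10000/3 draws, 50000
  trees).
* Weight is analysed on the raw mg scale and microbiome covariates enter the
  weight ladder unstandardized; DIC differences are invariant to these
  scalings under the diffuse priors used.
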