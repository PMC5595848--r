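#' Configuration for the synthetic rearing-study generator
#'
#' Defaults emulate the design of a two-population (BST, HWR) x two-host-plant
#' (Me = alfalfa, Lu = L. argenteus) rearing experiment: 181 caterpillars
#' assigned to treatments in (approximately) equal proportion, frass sampled
#' at 15/20/25 days from survivors, a subset of caterpillars sacrificed for
#' whole-larva samples, plant epiphyte/endophyte samples, lognormal library
#' sizes with amplification failures, a Wolbachia spike in whole-caterpillar
#' samples (mean relative abundance 0.37, s.d. 0.36; essentially absent from
#' frass), an age-dependent decline in effective phylotype diversity
#' (-0.151 effective species per day), a plant effect on weight
#' (beta_plant = -0.961 mg, beta_age = 0.225 mg/day) and population/plant
#' effects on survival to 15 days (beta_pop = -0.56, beta_plant(Lu) = -0.15
#' on the logit scale, intercept -0.49, giving ~31% marginal survival).
#'
#' @param nCaterpillars number of neonate larvae reared.
#' @param nFamilies maternal families (population assigned per family).
#' @param ages sampling ages in days.
#' @param nOtus number of community (bacterial) OTUs.
#' @param concentrationTotal total Dirichlet concentration of the base
#'   community (controls sample-to-sample compositional noise).
#' @param evennessRatio geometric decay ratio of the base composition
#'   (abundance of OTU i+1 relative to OTU i); controls baseline diversity.
#' @param groupMultipliers optional 4 x nOtus matrix of per-treatment
#'   concentration multipliers (rows HWR_Me, HWR_Lu, BST_Me, BST_Lu); default
#'   boosts a few taxonomic orders per plant / population.
#' @param typeMultiplier optional length-nOtus multiplier applied to
#'   whole-larva samples (compositional shift of larvae vs frass).
#' @param wolbachiaMean,wolbachiaSd target relative abundance of the
#'   designated Wolbachia OTU in whole-larva samples. Setting
#'   `wolbachiaMean = 0` removes Wolbachia from every sample.
#' @param wolbachiaFrassMean,wolbachiaFrassSd trace Wolbachia carry-over in
#'   frass.
#' @param ageDiversitySlope change in expected effective phylotype diversity
#'   (inverse Simpson at `calibrationDepth`) per day of larval age.
#' @param calibrationDepth depth at which the diversity-age line is
#'   calibrated (the second-stage rarefaction depth).
#' @param depthLognormal meanlog/sdlog of library sizes for samples that
#'   amplify.
#' @param amplificationFailureProb probability a sample yields too few
#'   sequences; failed samples draw a depth uniformly from
#'   `failedDepthRange`.
#' @param failedDepthRange depth range for failed amplifications (below the
#'   first-stage rarefaction cutoff).
#' @param weightModel named vector b0, b_plant (Me = 1), b_pop (BST = 1),
#'   b_age (per day), residual_sd; weight in mg.
#' @param survivalModel named vector a0, a_pop (BST = 1), a_plant (Lu = 1) on
#'   the logit scale for survival to 15 days.
#' @param sacrificeProb per-age probability that a living caterpillar is
#'   sacrificed for a whole-larva sample at that age.
#' @param interAgeSurvival probability a caterpillar survives each 5-day
#'   interval after day 15.
#' @param plantReps replicate leaf collections per plant species x sample
#'   type.
#' @param organelleFraction concentrations (as fractions of
#'   `concentrationTotal`) of chloroplast, mitochondrial and unassigned
#'   sequences in frass/larva samples.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(nCaterpillars = 181L,
                             nFamilies = 20L,
                             ages = c(15L, 20L, 25L),
                             nOtus = 60L,
                             concentrationTotal = 100,
                             evennessRatio = 0.75,
                             groupMultipliers = NULL,
                             typeMultiplier = NULL,
                             wolbachiaMean = 0.37,
                             wolbachiaSd = 0.36,
                             wolbachiaFrassMean = 7e-4,
                             wolbachiaFrassSd = 0.003,
                             ageDiversitySlope = -0.151,
                             calibrationDepth = 500L,
                             depthLognormal = c(meanlog = 8.25, sdlog = 1.0),
                             amplificationFailureProb = 0.52,
                             failedDepthRange = c(30L, 1310L),
                             weightModel = c(b0 = 3, b_plant = -0.961,
                                             b_pop = -0.3, b_age = 0.225,
                                             residual_sd = 1),
                             survivalModel = c(a0 = -0.49, a_pop = -0.56,
                                               a_plant = -0.15),
                             sacrificeProb = c(`15` = 0.25, `20` = 0.4,
                                               `25` = 0.4),
                             interAgeSurvival = 0.9,
                             plantReps = 3L,
                             organelleFraction = c(chloroplast = 0.015,
                                                   mitochondria = 0.005,
                                                   unassigned = 0.01),
                             seed = 1L) {
  cfg <- list(nCaterpillars = as.integer(nCaterpillars),
              nFamilies = as.integer(nFamilies), ages = as.integer(ages),
              nOtus = as.integer(nOtus),
              concentrationTotal = concentrationTotal,
              evennessRatio = evennessRatio,
              groupMultipliers = groupMultipliers,
              typeMultiplier = typeMultiplier,
              wolbachiaMean = wolbachiaMean, wolbachiaSd = wolbachiaSd,
              wolbachiaFrassMean = wolbachiaFrassMean,
              wolbachiaFrassSd = wolbachiaFrassSd,
              ageDiversitySlope = ageDiversitySlope,
              calibrationDepth = as.integer(calibrationDepth),
              depthLognormal = depthLognormal,
              amplificationFailureProb = amplificationFailureProb,
              failedDepthRange = failedDepthRange,
              weightModel = weightModel, survivalModel = survivalModel,
              sacrificeProb = sacrificeProb,
              interAgeSurvival = interAgeSurvival,
              plantReps = as.integer(plantReps),
              organelleFraction = organelleFraction,
              seed = as.integer(seed))
  stopifnot(cfg$nCaterpillars >= 1, cfg$nOtus >= 2,
            cfg$concentrationTotal > 0,
            cfg$evennessRatio > 0, cfg$evennessRatio < 1,
            wolbachiaMean >= 0, wolbachiaMean < 1,
            amplificationFailureProb >= 0, amplificationFailureProb <= 1,
            all(sacrificeProb >= 0), all(sacrificeProb <= 1),
            interAgeSurvival >= 0, interAgeSurvival <= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

# Treatment table: population x plant, equal allocation.
treatmentTable <- function() {
  data.frame(population = c("HWR", "HWR", "BST", "BST"),
             plant = c("Me", "Lu", "Me", "Lu"),
             group = c("HWR_Me", "HWR_Lu", "BST_Me", "BST_Lu"),
             stringsAsFactors = FALSE)
}

# Community taxonomy: OTUs cycle through common caterpillar-gut orders so
# that treatment effects can be attached to named orders.
communityTaxonomy <- function(nOtus) {
  orders <- data.frame(
    phylum = c("Firmicutes", "Proteobacteria", "Proteobacteria",
               "Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Actinobacteria", "Bacteroidetes"),
    class = c("Bacilli", "Alphaproteobacteria", "Gammaproteobacteria",
              "Alphaproteobacteria", "Gammaproteobacteria",
              "Alphaproteobacteria", "Actinobacteria", "Flavobacteriia"),
    order = c("Lactobacillales", "Rhodospirillales", "Pseudomonadales",
              "Rhizobiales", "Enterobacteriales", "Sphingomonadales",
              "Actinomycetales", "Flavobacteriales"),
    stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(orders)), length.out = nOtus)
  sprintf("k__Bacteria; p__%s; c__%s; o__%s; f__f%d; g__g%d",
          orders$phylum[idx], orders$class[idx], orders$order[idx],
          seq_len(nOtus), seq_len(nOtus))
}

specialTaxonomy <- function() {
  c(wolbachia = paste0("k__Bacteria; p__Proteobacteria; ",
                       "c__Alphaproteobacteria; o__Rickettsiales; ",
                       "f__Anaplasmataceae; g__Wolbachia"),
    chloroplast1 = "k__Bacteria; p__Cyanobacteria; c__Chloroplast; o__Streptophyta",
    chloroplast2 = "k__Bacteria; p__Cyanobacteria; c__Chloroplast; o__Chlorophyta",
    mitochondria = paste0("k__Bacteria; p__Proteobacteria; ",
                          "c__Alphaproteobacteria; o__Rickettsiales; ",
                          "f__mitochondria"),
    unassigned = "Unassigned")
}

# Default per-treatment concentration multipliers: a few orders respond to
# plant or population, mirroring the kind of order-level differential
# abundance the model is meant to detect.
defaultGroupMultipliers <- function(taxonomy, nOtus) {
  parsed <- parseLineage(taxonomy)
  tt <- treatmentTable()
  mult <- matrix(1, nrow(tt), nOtus, dimnames = list(tt$group, NULL))
  ord <- parsed$order
  mult[tt$plant == "Lu", ord == "Lactobacillales"] <- 4
  mult[tt$plant == "Lu", ord == "Rhodospirillales"] <- 3
  mult[tt$plant == "Me", ord == "Pseudomonadales"] <- 3
  mult[tt$population == "BST", ord == "Rhizobiales"] <- 6
  mult[tt$group == "HWR_Lu", ord == "Enterobacteriales"] <- 3
  mult
}

defaultTypeMultiplier <- function(nOtus) {
  # whole larvae enriched for a handful of OTUs relative to frass
  mult <- rep(1, nOtus)
  mult[seq(3, nOtus, by = 11)] <- 2.5
  mult
}

# Beta distribution parameters matched to a (mean, sd) target.
betaParams <- function(m, s) {
  v <- min(s^2, 0.95 * m * (1 - m))
  nu <- m * (1 - m) / v - 1
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

# Closed-form expected Simpson concentration (sum p_hat^2) of rarefied
# counts at `depth` when pi ~ Dirichlet(alpha):
# E[sum p_hat^2] = (1 - 1/d) * sum a_i(a_i + 1) / (A (A + 1)) + 1/d.
expectedSimpson <- function(alpha, depth) {
  A <- sum(alpha)
  s2 <- sum(alpha * (alpha + 1)) / (A * (A + 1))
  (1 - 1 / depth) * s2 + 1 / depth
}

# Exponent t on the concentration vector such that the expected inverse
# Simpson diversity at `depth` hits `targetD`; t > 1 sharpens the
# composition (lower diversity), t < 1 flattens it.
calibrateExponent <- function(alpha, targetD, depth) {
  f <- function(t) 1 / expectedSimpson(alpha^t, depth) - targetD
  lo <- 0.2; hi <- 8
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Analytic marginal survival of the generator
#'
#' Mean of the four treatment-cell survival probabilities under equal
#' allocation; the defaults give ~0.30, matching the observed 31% survival
#' to 15 days.
#'
#' @param config a [simulationConfig()].
#' @return probability.
#' @export
expectedSurvival <- function(config = simulationConfig()) {
  tt <- treatmentTable()
  sv <- config$survivalModel
  mean(stats::plogis(sv["a0"] + sv["a_pop"] * (tt$population == "BST") +
                       sv["a_plant"] * (tt$plant == "Lu")))
}

#' Simulate a full rearing study
#'
#' Generates caterpillars, survival, sampling schedule, OTU counts, weights
#' and metadata under the model described in [simulationConfig()]. Counts for
#' each sample are multinomial draws at a lognormal library size from a
#' Dirichlet composition whose concentration vector combines the treatment
#' base community, a whole-larva shift, an age-calibrated evenness exponent
#' and (for larvae) a Beta-distributed Wolbachia admixture. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return a [SimulatedStudy-class]: the [OtuExperiment-class] (sample
#'   metadata in `colData`), the per-caterpillar survival table and a `truth`
#'   list holding all generative parameters, per-sample depths and realized
#'   compositions.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  set.seed(config$seed)
  tt <- treatmentTable()
  K <- config$nOtus
  commTax <- communityTaxonomy(K)
  spTax <- specialTaxonomy()
  otuIds <- c(sprintf("OTU_%03d", seq_len(K)), names(spTax))
  taxAll <- c(commTax, unname(spTax))
  warnings <- character()

  # base community: geometric composition scaled to the concentration total
  p <- config$evennessRatio^(seq_len(K) - 1)
  alphaBase <- config$concentrationTotal * p / sum(p)
  gm <- config$groupMultipliers %||% defaultGroupMultipliers(commTax, K)
  tm <- config$typeMultiplier %||% defaultTypeMultiplier(K)
  groupAlpha <- sweep(gm, 2, alphaBase, `*`)
  rownames(groupAlpha) <- tt$group

  # age-evenness exponents per (group, type), anchored at age 15
  exponents <- array(1, c(nrow(tt), 2, length(config$ages)),
                     dimnames = list(tt$group, c("frass", "larva"),
                                     config$ages))
  for (g in seq_len(nrow(tt))) for (ty in 1:2) {
    a <- groupAlpha[g, ] * (if (ty == 2) tm else 1)
    d15 <- 1 / expectedSimpson(a, config$calibrationDepth)
    for (j in seq_along(config$ages)) {
      target <- d15 + config$ageDiversitySlope * (config$ages[j] - 15)
      exponents[g, ty, j] <-
        if (config$ages[j] == 15) 1
        else calibrateExponent(a, max(target, 1.05), config$calibrationDepth)
    }
  }

  # caterpillars: population via family, plant alternating at hatching
  fams <- data.frame(family_id = sprintf("fam%02d", seq_len(config$nFamilies)),
                     population = rep(c("BST", "HWR"),
                                      length.out = config$nFamilies))
  cats <- data.frame(
    caterpillar_id = sprintf("cat%03d", seq_len(config$nCaterpillars)),
    family_id = fams$family_id[sample.int(config$nFamilies,
                                          config$nCaterpillars,
                                          replace = TRUE)],
    plant = rep(c("Me", "Lu"), length.out = config$nCaterpillars),
    stringsAsFactors = FALSE)
  cats$population <- fams$population[match(cats$family_id, fams$family_id)]
  sv <- config$survivalModel
  cats$p_survival <- stats::plogis(
    sv["a0"] + sv["a_pop"] * (cats$population == "BST") +
      sv["a_plant"] * (cats$plant == "Lu"))
  cats$survived_15d <- stats::runif(config$nCaterpillars) < cats$p_survival
  cats$group <- paste(cats$population, cats$plant, sep = "_")
  emptyCells <- setdiff(tt$group, unique(cats$group))
  if (length(emptyCells))
    warnings <- c(warnings, paste("treatment cell(s) with zero caterpillars:",
                                  paste(emptyCells, collapse = ", ")))

  # sampling schedule: frass at every age while alive; sacrifices produce a
  # whole-larva sample and end the series; extra attrition between ages
  schedule <- list()
  alive <- cats$survived_15d
  for (j in seq_along(config$ages)) {
    age <- config$ages[j]
    if (j > 1) alive <- alive & (stats::runif(nrow(cats)) <
                                   config$interAgeSurvival)
    idx <- which(alive)
    for (i in idx)
      schedule[[length(schedule) + 1]] <-
        data.frame(caterpillar_id = cats$caterpillar_id[i],
                   sample_type = "frass", age_days = age)
    sac <- idx[stats::runif(length(idx)) <
                 config$sacrificeProb[as.character(age)]]
    for (i in sac)
      schedule[[length(schedule) + 1]] <-
        data.frame(caterpillar_id = cats$caterpillar_id[i],
                   sample_type = "larva", age_days = age)
    alive[sac] <- FALSE
  }
  sched <- do.call(rbind, schedule)

  # plant samples: epiphyte/endophyte per plant species (Me at both sites,
  # Lu only at HWR), plantReps replicates each
  plantRows <- expand.grid(plant = c("Me", "Lu"),
                           sample_type = c("plant_epiphyte",
                                           "plant_endophyte"),
                           rep = seq_len(config$plantReps),
                           stringsAsFactors = FALSE)
  plantRows$population <- ifelse(plantRows$plant == "Lu", "HWR",
                                 rep(c("BST", "HWR"),
                                     length.out = nrow(plantRows)))

  wLarva <- if (config$wolbachiaMean > 0)
    betaParams(config$wolbachiaMean, config$wolbachiaSd) else NULL
  wFrass <- if (config$wolbachiaMean > 0 && config$wolbachiaFrassMean > 0)
    betaParams(config$wolbachiaFrassMean, config$wolbachiaFrassSd) else NULL

  ofr <- config$organelleFraction
  organelleAlpha <- config$concentrationTotal *
    c(ofr["chloroplast"] / 2, ofr["chloroplast"] / 2, ofr["mitochondria"],
      ofr["unassigned"])
  # plant community: chloroplast-dominated, thin overlap with the gut pool
  plantAlphaBase <- c(0.25 * alphaBase,
                      config$concentrationTotal * c(2.0, 0.5, 0.15, 0.02))

  n <- nrow(sched) + nrow(plantRows)
  countMat <- matrix(0, length(otuIds), n, dimnames = list(otuIds, NULL))
  meta <- vector("list", n)
  depths <- numeric(n)
  wDraws <- numeric(n)
  sampleIds <- character(n)
  wm <- config$weightModel

  drawDepth <- function() {
    if (stats::runif(1) < config$amplificationFailureProb)
      sample(config$failedDepthRange[1]:config$failedDepthRange[2], 1)
    else
      max(10, round(stats::rlnorm(1, config$depthLognormal["meanlog"],
                                  config$depthLognormal["sdlog"])))
  }

  for (s in seq_len(n)) {
    if (s <= nrow(sched)) {
      row <- sched[s, ]
      ci <- match(row$caterpillar_id, cats$caterpillar_id)
      g <- match(cats$group[ci], tt$group)
      ty <- if (row$sample_type == "larva") 2L else 1L
      aj <- match(row$age_days, config$ages)
      alphaComm <- (groupAlpha[g, ] * (if (ty == 2) tm else 1))^
        exponents[g, ty, aj]
      alpha <- c(alphaComm, organelleAlpha)
      pi0 <- as.numeric(rdirichlet(1, alpha))
      wpars <- if (ty == 2) wLarva else wFrass
      w <- if (is.null(wpars)) 0
      else min(stats::rbeta(1, wpars[1], wpars[2]), 1 - 1e-9)
      piFull <- c((1 - w) * pi0[seq_len(K)], w,
                  (1 - w) * pi0[K + 1:4])
      sampleIds[s] <- sprintf("%s_%s_%d",
                              ifelse(ty == 2, "L", "F"),
                              row$caterpillar_id, row$age_days)
      weight <- wm["b0"] + wm["b_plant"] * (cats$plant[ci] == "Me") +
        wm["b_pop"] * (cats$population[ci] == "BST") +
        wm["b_age"] * row$age_days +
        (if (wm["residual_sd"] > 0) stats::rnorm(1, 0, wm["residual_sd"])
         else 0)
      meta[[s]] <- data.frame(
        sample_type = row$sample_type, population = cats$population[ci],
        plant = cats$plant[ci], age_days = row$age_days,
        weight_mg = unname(weight), survived_15d = TRUE,
        family_id = cats$family_id[ci],
        caterpillar_id = row$caterpillar_id, stringsAsFactors = FALSE)
    } else {
      row <- plantRows[s - nrow(sched), ]
      pi0 <- as.numeric(rdirichlet(1, plantAlphaBase))
      w <- 0
      piFull <- c(pi0[seq_len(K)], 0, pi0[K + 1:4])
      sampleIds[s] <- sprintf("P_%s_%s_%d", row$plant,
                              sub("plant_", "", row$sample_type), row$rep)
      meta[[s]] <- data.frame(
        sample_type = row$sample_type, population = row$population,
        plant = row$plant, age_days = NA_integer_, weight_mg = NA_real_,
        survived_15d = NA, family_id = NA_character_,
        caterpillar_id = NA_character_, stringsAsFactors = FALSE)
    }
    wDraws[s] <- w
    depths[s] <- drawDepth()
    countMat[, s] <- stats::rmultinom(1, depths[s], piFull)[, 1]
  }

  colnames(countMat) <- sampleIds
  metaDf <- do.call(rbind, meta)
  metaDf <- cbind(sample_id = sampleIds, metaDf)
  rownames(metaDf) <- sampleIds
  otu <- OtuExperiment(countMat, taxAll, sampleData = metaDf)

  truth <- list(config = config, groupAlpha = groupAlpha,
                typeMultiplier = tm, exponents = exponents,
                organelleAlpha = organelleAlpha,
                plantAlpha = plantAlphaBase,
                groupComposition = groupAlpha / rowSums(groupAlpha),
                survivalProbs = stats::setNames(
                  unique(cats[c("group", "p_survival")])$p_survival,
                  unique(cats[c("group", "p_survival")])$group),
                expectedSurvival = expectedSurvival(config),
                depths = stats::setNames(depths, sampleIds),
                wolbachiaWeight = stats::setNames(wDraws, sampleIds),
                warnings = warnings)
  new("SimulatedStudy", otu = otu,
      caterpillars = cats[c("caterpillar_id", "family_id", "population",
                            "plant", "p_survival", "survived_15d")],
      truth = truth)
}

#' Multinomial counts for one sample
#'
#' @param pi probability vector (must be non-negative and sum to 1).
#' @param depth total count.
#' @param seed integer seed.
#' @return integer count vector summing to `depth`.
#' @export
simulateDmCounts <- function(pi, depth, seed = 1L) {
  if (any(pi < 0)) stop("pi must be non-negative")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  stopifnot(depth >= 0)
  if (depth == 0) return(rep(0L, length(pi)))
  withSeed(seed, stats::rmultinom(1, depth, pi)[, 1])
}

#' Write a simulated study to disk
#'
#' Emits the OTU-table TSV, the metadata TSV and a JSON file with all
#' generative truth parameters.
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeOtuTable(study@otu, file.path(dir, "otu_table.tsv"))
  writeSampleMetadata(
    as.data.frame(SummarizedExperiment::colData(study@otu)),
    file.path(dir, "metadata.tsv"))
  truth <- study@truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

setMethod("show", "SimulatedStudy", function(object) {
  md <- SummarizedExperiment::colData(object@otu)
  cat("SimulatedStudy:", nrow(object@caterpillars), "caterpillars,",
      ncol(object@otu), "samples\n")
  print(table(md$sample_type))
})
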