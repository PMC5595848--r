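#' Pipeline configuration
#'
#' Collects the tunables of the end-to-end analysis: two-stage filtering and
#' rarefaction depths (1311 then 500), ordination axes, diversity order,
#' MCMC schedule, the differential-abundance subset rule (frass samples at
#' 15-20 days, groups = population x plant, groups with < 2 samples dropped)
#' and random-forest settings.
#'
#' @param stage1Depth,stage2Depth rarefaction depths for the all-sample and
#'   the gut-community stage.
#' @param minRelAbund rare-OTU threshold for the second stage.
#' @param nAxes ordination axes carried into the models.
#' @param q Hill diversity order.
#' @param daAges caterpillar ages (days) whose frass enters the
#'   differential-abundance subset.
#' @param daMinN minimum samples per treatment group in that subset.
#' @param alpha0 Dirichlet prior concentration.
#' @param daDraws posterior draws for the multinomial-Dirichlet models.
#' @param rfTrees random-forest tree count (the full analysis uses 50000).
#' @param settings an [mcmcSettings()] used for every MCMC model.
#' @param prior a [priorSpec()].
#' @param seed global seed; all stage seeds derive from it.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(stage1Depth = 1311L, stage2Depth = 500L,
                           minRelAbund = 0.01, nAxes = 2L, q = 2,
                           daAges = c(15L, 20L), daMinN = 2L, alpha0 = 1,
                           daDraws = 10000L, rfTrees = 50000L,
                           settings = mcmcSettings(), prior = priorSpec(),
                           seed = 1L) {
  structure(list(stage1Depth = as.integer(stage1Depth),
                 stage2Depth = as.integer(stage2Depth),
                 minRelAbund = minRelAbund, nAxes = as.integer(nAxes), q = q,
                 daAges = as.integer(daAges), daMinN = as.integer(daMinN),
                 alpha0 = alpha0, daDraws = as.integer(daDraws),
                 rfTrees = as.integer(rfTrees), settings = settings,
                 prior = prior, seed = as.integer(seed)),
            class = "PipelineConfig")
}

pipelineStage <- function(report, stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("pipelineError", "error", "condition"),
                   list(message = sprintf(
                     "pipeline stage '%s' failed: %s (completed stages: %s)",
                     stage, conditionMessage(e),
                     paste(names(report), collapse = ", ")),
                     call = NULL, partialReport = report)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: organelle/unassigned filtering and rarefaction (stage
#' 1); all-sample chord-PCA, Bray-Curtis PCoA, Hill diversity, per-sample-type
#' Bayesian group models (epiphytes and endophytes pooled as "plant") and
#' random-forest sample-type classification; removal of plant samples,
#' Wolbachia and rare OTUs followed by re-rarefaction (stage 2); UPGMA
#' clustering, frass/larva ordination and diversity, Bayesian linear models of
#' PC/PCO/diversity on type + plant + population + age, random-forest
#' classification of type/plant/population/age; multinomial-Dirichlet
#' differential abundance with posterior-predictive RMSE model comparison on
#' the 15-20-day frass subset; a Bernoulli-logit survival model; and a
#' DIC-ranked ladder of weight models with microbiome covariates and
#' microbiome x plant interactions. Binary covariates are coded type: larva =
#' 1, plant: Me = 1 (Lu = 1 in the survival model, where L. argenteus lowers
#' survival), population: BST = 1; age stays in raw days.
#'
#' @param study a [SimulatedStudy-class], or an [OtuExperiment-class] whose
#'   `colData` carries the metadata columns (sample_type, population, plant,
#'   age_days, weight_mg).
#' @param config a [pipelineConfig()].
#' @param caterpillars optional per-caterpillar table with columns
#'   population, plant, survived_15d for the survival model (taken from the
#'   study when a [SimulatedStudy-class] is supplied).
#' @param outdir optional directory; when given, a JSON report manifest,
#'   per-analysis TSVs and the UPGMA newick are written there.
#' @return a nested report list (also written as JSON when `outdir` is set).
#' @export
runPipeline <- function(study, config = pipelineConfig(),
                        caterpillars = NULL, outdir = NULL) {
  if (is(study, "SimulatedStudy")) {
    otu <- study@otu
    caterpillars <- caterpillars %||% study@caterpillars
  } else otu <- study
  md <- as.data.frame(SummarizedExperiment::colData(otu))
  report <- list()
  seed <- config$seed

  # ---- stage 1: organelle filter + rarefaction, all samples --------------
  report$accounting <- list(input = list(samples = ncol(otu),
                                         otus = nrow(otu)))
  stage1 <- pipelineStage(report, "stage1_filter_rarefy", {
    flt <- filterTaxa(otu, organelleRules())
    rar <- rarefy(flt, config$stage1Depth, seed = stringSeed(seed, "rar1"))
    list(flt = flt, rar = rar)
  })
  report$accounting$stage1 <- list(
    otus_removed = nrow(otu) - nrow(stage1$flt),
    samples_dropped = length(droppedSamples(stage1$rar)),
    samples_retained = ncol(stage1$rar),
    dropped_ids = droppedSamples(stage1$rar))

  md1 <- as.data.frame(SummarizedExperiment::colData(stage1$rar))
  typeGroup <- ifelse(grepl("^plant", md1$sample_type), "plant",
                      md1$sample_type)

  all1 <- pipelineStage(report, "stage1_ordination_diversity", {
    rel <- relativeAbundance(stage1$rar)
    pca <- pcaOrdination(chordTransform(rel), config$nAxes)
    pco <- pcoaOrdination(brayCurtis(rel), config$nAxes)
    div <- hillDiversity(rel, config$q)
    list(rel = rel, pca = pca, pco = pco, div = div)
  })
  report$stage1_ordination <- list(
    pca_explained = all1$pca@explained, pcoa_explained = all1$pco@explained,
    diversity_mean = mean(all1$div))

  report$stage1_group_models <- pipelineStage(report, "stage1_group_models", {
    metrics <- cbind(all1$pca@scores[, seq_len(config$nAxes), drop = FALSE],
                     all1$pco@scores[, seq_len(config$nAxes), drop = FALSE],
                     D2 = as.numeric(all1$div))
    fits <- lapply(colnames(metrics), function(mt)
      fitGroupModel(metrics[, mt], typeGroup, config$prior,
                    settingsWithSeed(config$settings,
                                     stringSeed(seed, paste0("gm_", mt)))))
    names(fits) <- colnames(metrics)
    lapply(fits, function(f) f@summary)
  })

  report$stage1_rf <- pipelineStage(report, "stage1_rf", {
    rf <- rfClassify(all1$rel, typeGroup, nTrees = config$rfTrees,
                     seed = stringSeed(seed, "rf1"), task = "sample_type")
    rfReport(rf)
  })

  # ---- stage 2: gut-community table --------------------------------------
  stage2 <- pipelineStage(report, "stage2_filter_rarefy", {
    gut <- stage1$flt[, !grepl("^plant", md$sample_type)]
    gut <- filterTaxa(gut, hostFilterRules())
    gut <- filterRareOtus(gut, config$minRelAbund)
    rarefy(gut, config$stage2Depth, seed = stringSeed(seed, "rar2"))
  })
  report$accounting$stage2 <- list(
    samples_dropped = length(droppedSamples(stage2)),
    samples_retained = ncol(stage2), otus_retained = nrow(stage2),
    dropped_ids = droppedSamples(stage2))

  md2 <- as.data.frame(SummarizedExperiment::colData(stage2))
  gut2 <- pipelineStage(report, "stage2_ordination_diversity", {
    rel <- relativeAbundance(stage2)
    bc <- brayCurtis(rel)
    list(rel = rel, bc = bc,
         pca = pcaOrdination(chordTransform(rel), config$nAxes),
         pco = pcoaOrdination(bc, config$nAxes),
         div = hillDiversity(rel, config$q),
         upgma = upgmaTree(bc))
  })
  report$stage2_ordination <- list(
    pca_explained = gut2$pca@explained, pcoa_explained = gut2$pco@explained,
    upgma_newick = gut2$upgma$newick)

  design2 <- data.frame(type = as.numeric(md2$sample_type == "larva"),
                        plant = as.numeric(md2$plant == "Me"),
                        pop = as.numeric(md2$population == "BST"),
                        age = md2$age_days)
  lmFits <- pipelineStage(report, "stage2_linear_models", {
    metrics <- cbind(gut2$pca@scores[, seq_len(config$nAxes), drop = FALSE],
                     gut2$pco@scores[, seq_len(config$nAxes), drop = FALSE],
                     D2 = as.numeric(gut2$div))
    fits <- lapply(colnames(metrics), function(mt)
      fitLinearModel(metrics[, mt], design2, config$prior,
                     settingsWithSeed(config$settings,
                                      stringSeed(seed, paste0("lm_", mt)))))
    names(fits) <- colnames(metrics)
    fits
  })
  report$stage2_linear_models <- lapply(lmFits, function(f)
    cbind(f@coefficients, dic = unname(f@dic["DIC"])))

  report$stage2_rf <- pipelineStage(report, "stage2_rf", {
    tasks <- list(sample_type = md2$sample_type, plant = md2$plant,
                  population = md2$population,
                  age = as.character(md2$age_days))
    out <- list()
    for (tk in names(tasks)) {
      lab <- tasks[[tk]]
      if (length(unique(lab)) < 2 || any(table(lab) < 2)) next
      out[[tk]] <- rfReport(rfClassify(
        gut2$rel, lab, nTrees = config$rfTrees,
        seed = stringSeed(seed, paste0("rf2_", tk)), task = tk))
    }
    out
  })

  # ---- differential abundance on the 15-20 day frass subset --------------
  report$differential_abundance <-
    pipelineStage(report, "differential_abundance", {
      sel <- md2$sample_type == "frass" & md2$age_days %in% config$daAges
      sub <- stage2[, sel]
      grp <- paste(md2$population[sel], md2$plant[sel], sep = "_")
      keep <- grp %in% names(which(table(grp) >= config$daMinN))
      sub <- sub[, keep]
      grp <- grp[keep]
      fit <- fitDirichletMultinomial(sub, grp, config$alpha0,
                                     config$daDraws,
                                     seed = stringSeed(seed, "da"))
      probs <- otuDifferenceProbs(fit)
      rmse <- ppRmseCompare(sub, grp, config$alpha0, config$daDraws,
                            seed = stringSeed(seed, "pprmse"))
      list(groups = table(grp), summary = fit@summary,
           difference_probs = probs,
           flagged_otus = unique(probs$otu[probs$flagged]),
           pp_full_better = rmse@ppFullBetter,
           rmse_full_pm = stats::median(rmse@rmseFull),
           rmse_null_pm = stats::median(rmse@rmseNull))
    })

  # ---- larval performance -------------------------------------------------
  report$survival <- pipelineStage(report, "survival_model", {
    if (is.null(caterpillars)) return(NULL)
    dsn <- data.frame(pop = as.numeric(caterpillars$population == "BST"),
                      plant = as.numeric(caterpillars$plant == "Lu"))
    fit <- fitLogisticModel(caterpillars$survived_15d, dsn, config$prior,
                            settingsWithSeed(config$settings,
                                             stringSeed(seed, "surv")))
    cells <- unique(dsn)
    list(coefficients = fit@coefficients,
         survival_fraction = mean(caterpillars$survived_15d),
         fitted = cbind(
           unique(caterpillars[c("population", "plant")]),
           fittedProbabilities(fit, cells)[c("pm", "lower", "upper")]),
         dic = fit@dic)
  })

  report$weight_models <- pipelineStage(report, "weight_models", {
    sel <- md2$sample_type == "frass" & md2$age_days %in% c(15L, 20L) &
      !is.na(md2$weight_mg)
    if (sum(sel) < 8) return(NULL)
    mic <- cbind(gut2$pca@scores[sel, seq_len(config$nAxes), drop = FALSE],
                 gut2$pco@scores[sel, seq_len(config$nAxes), drop = FALSE],
                 D2 = as.numeric(gut2$div)[sel])
    base <- data.frame(plant = as.numeric(md2$plant[sel] == "Me"),
                       pop = as.numeric(md2$population[sel] == "BST"),
                       age = md2$age_days[sel])
    ladder <- weightModelLadder(md2$weight_mg[sel], base, mic,
                                prior = config$prior,
                                settings = settingsWithSeed(
                                  config$settings,
                                  stringSeed(seed, "ladder")))
    list(table = ladder$table, n = sum(sel),
         base_coefficients = ladder$fits[["base"]]@coefficients)
  })

  if (!is.null(outdir))
    writePipelineReport(report, all1, gut2, outdir)
  report
}

settingsWithSeed <- function(settings, seed)
  mcmcSettings(settings@nChains, settings@burnIn, settings@nIter,
               settings@thin, seed)

rfReport <- function(rf) {
  list(oob_accuracy = rf@oobAccuracy, confusion = rf@confusion,
       top_otus = utils::head(rf@importance, 10))
}

#' DIC ladder of weight models
#'
#' Fits the base weight model (plant + population + age) plus, for each
#' microbiome covariate supplied (PC/PCO scores, diversity), the base model
#' augmented with that covariate and with its plant interaction, and ranks
#' all models by DIC. The base model is always present in the ladder.
#'
#' @param weights response (mg), 15/20-day caterpillars.
#' @param base data.frame with plant, pop, age columns (0/1 dummies, raw
#'   days).
#' @param microbiome data.frame/matrix of per-sample microbiome covariates.
#' @param prior,settings passed to [fitLinearModel()].
#' @return list: `table` (model, DIC, pD, sorted by DIC), `fits` (the
#'   [RegressionFit-class] objects), `best` (name of the lowest-DIC model).
#' @export
weightModelLadder <- function(weights, base, microbiome = NULL,
                              prior = priorSpec(),
                              settings = mcmcSettings()) {
  designs <- list(base = base)
  if (!is.null(microbiome)) {
    microbiome <- as.data.frame(microbiome)
    for (v in colnames(microbiome)) {
      designs[[v]] <- cbind(base, microbiome[v])
      inter <- base
      inter[[v]] <- microbiome[[v]]
      inter[[paste0(v, ":plant")]] <- microbiome[[v]] * base$plant
      designs[[paste0(v, "_x_plant")]] <- inter
    }
  }
  fits <- lapply(seq_along(designs), function(i)
    fitLinearModel(weights, designs[[i]], prior,
                   settingsWithSeed(settings, settings@seed + 101L * i)))
  names(fits) <- names(designs)
  tab <- data.frame(model = names(designs),
                    dic = vapply(fits, function(f) f@dic[["DIC"]], 0),
                    pd = vapply(fits, function(f) f@dic[["pD"]], 0),
                    row.names = NULL)
  tab <- tab[order(tab$dic), ]
  list(table = tab, fits = fits, best = tab$model[1])
}

writePipelineReport <- function(report, all1, gut2, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeLines(gut2$upgma$newick, file.path(outdir, "upgma.nwk"))
  utils::write.table(
    data.frame(sample_id = rownames(gut2$pca@scores), gut2$pca@scores,
               gut2$pco@scores, D2 = as.numeric(gut2$div)),
    file.path(outdir, "scores_gut.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(all1$pca@scores), all1$pca@scores,
               D2 = as.numeric(all1$div)),
    file.path(outdir, "scores_all.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$differential_abundance))
    utils::write.table(report$differential_abundance$difference_probs,
                       file.path(outdir, "da_difference_probs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
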