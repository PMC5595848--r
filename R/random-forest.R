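#' Random-forest classification of samples
#'
#' Classifies samples (e.g. by sample type, plant, population or age) from
#' their OTU relative abundances with a random forest (GINI split criterion,
#' sqrt(K) candidate features per split, out-of-bag evaluation), and ranks
#' OTUs by mean decrease in GINI impurity. Deterministic given `seed`.
#'
#' @param features samples x OTUs numeric matrix (typically relative
#'   abundances).
#' @param labels class label per sample; >= 2 classes with >= 2 members each.
#' @param nTrees number of trees (50000 in the full analysis; reduce for
#'   quick runs).
#' @param seed integer seed.
#' @param task optional task name recorded in the result.
#' @return a [ClassificationResult-class].
#' @export
rfClassify <- function(features, labels, nTrees = 50000, seed = 1L,
                       task = "classification") {
  features <- as.matrix(features)
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (any(table(y) < 2)) stop("every class needs >= 2 samples")
  colnames(features) <- make.names(colnames(features))
  rf <- withSeed(seed, randomForest::randomForest(
    x = as.data.frame(features), y = y, ntree = nTrees))
  conf <- rf$confusion[, levels(y), drop = FALSE]
  pred <- rf$predicted
  # with very few trees some samples are never out-of-bag; they are excluded
  oob <- mean(pred == y, na.rm = TRUE)
  imp <- data.frame(otu = rownames(rf$importance),
                    gini = rf$importance[, "MeanDecreaseGini"],
                    row.names = NULL)
  imp <- imp[order(-imp$gini), ]
  new("ClassificationResult", task = task, confusion = conf,
      oobAccuracy = oob, importance = imp)
}

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("Random forest '%s': OOB accuracy %.3f\n", object@task,
              object@oobAccuracy))
  cat("  top OTUs by GINI importance:",
      paste(utils::head(object@importance$otu, 3), collapse = ", "), "\n")
})
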