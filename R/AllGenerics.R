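#' @export
setGeneric("taxonomy", function(x, ...) standardGeneric("taxonomy"))

#' @export
setGeneric("filterTaxa", function(x, exclude, ...) standardGeneric("filterTaxa"))

#' @export
setGeneric("filterRareOtus", function(x, minRelAbund = 0.01, ...)
  standardGeneric("filterRareOtus"))

#' @export
setGeneric("rarefy", function(x, depth, seed = 1L, ...)
  standardGeneric("rarefy"))

#' @export
setGeneric("relativeAbundance", function(x, ...)
  standardGeneric("relativeAbundance"))

#' @export
setGeneric("droppedSamples", function(x) standardGeneric("droppedSamples"))

#' @export
setGeneric("summarizePosterior", function(x, ...)
  standardGeneric("summarizePosterior"))

#' @export
setGeneric("gelmanRubin", function(x, ...) standardGeneric("gelmanRubin"))

#' @export
setGeneric("effectiveSampleSize", function(x, ...)
  standardGeneric("effectiveSampleSize"))

#' @export
setGeneric("mcmcDic", function(x, ...) standardGeneric("mcmcDic"))
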