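#' Construct an OtuExperiment
#'
#' @param counts integer matrix of OTU counts, OTUs as rows and samples as
#'   columns, with unique dimnames. (On disk and in community-ecology
#'   functions samples are rows; the container follows the Bioconductor
#'   feature-by-sample convention.)
#' @param taxonomy character vector of Greengenes-style lineage strings, one
#'   per OTU.
#' @param sampleData optional data.frame / DataFrame of per-sample metadata
#'   (rows matching `colnames(counts)`).
#' @return an [OtuExperiment-class] object.
#' @export
#' @examples
#' cnt <- matrix(rpois(12, 20), 4, 3,
#'               dimnames = list(paste0("otu", 1:4), paste0("s", 1:3)))
#' oe <- OtuExperiment(cnt, rep("k__Bacteria; p__Firmicutes", 4))
OtuExperiment <- function(counts, taxonomy, sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(taxonomy) != nrow(counts))
    stop("taxonomy length (", length(taxonomy),
         ") must equal the number of OTUs (", nrow(counts), ")")
  parsed <- parseLineage(taxonomy)
  rd <- S4Vectors::DataFrame(lineage = as.character(taxonomy),
                             parsed[setdiff(names(parsed), "raw")])
  rownames(rd) <- rownames(counts)
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd,
    colData = S4Vectors::DataFrame(sampleData))
  new("OtuExperiment", se)
}

#' @describeIn OtuExperiment access the count matrix (OTUs x samples).
#' @param object,x an OtuExperiment.
#' @export
setMethod("counts", "OtuExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @describeIn OtuExperiment taxonomy lineage strings, one per OTU.
#' @export
setMethod("taxonomy", "OtuExperiment", function(x)
  as.character(SummarizedExperiment::rowData(x)$lineage))

#' @describeIn OtuExperiment sample ids dropped by the last [rarefy()] call.
#' @export
setMethod("droppedSamples", "OtuExperiment", function(x)
  S4Vectors::metadata(x)$dropped_samples %||% character())

setMethod("show", "OtuExperiment", function(object) {
  cat("OtuExperiment:", nrow(object), "OTUs x", ncol(object), "samples\n")
  cat("  total counts:", sum(counts(object)),
      "| median sample depth:", stats::median(colSums(counts(object))), "\n")
  cv <- colnames(SummarizedExperiment::colData(object))
  if (length(cv)) cat("  sample covariates:", paste(cv, collapse = ", "), "\n")
})

#' Read an OTU table from disk
#'
#' The TSV dialect has OTUs as rows: first column the OTU id, last column the
#' taxonomy lineage, and one column per sample in between. A BIOM (JSON
#' dialect) reader is provided for interoperability (requires the
#' `biomformat` package).
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return an [OtuExperiment-class].
#' @export
readOtuTable <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom_json") return(readBiomTable(path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 3)
    stop("TSV must have an OTU id column, >=1 sample column and a taxonomy column")
  sampleIds <- colnames(df)[2:(ncol(df) - 1)]
  dup <- sampleIds[duplicated(sampleIds)]
  if (length(dup))
    stop("duplicate sample id(s) in header: ", paste(unique(dup), collapse = ", "))
  otuIds <- df[[1]]
  dup <- otuIds[duplicated(otuIds)]
  if (length(dup))
    stop("duplicate OTU id(s): ", paste(unique(dup), collapse = ", "))
  raw <- as.matrix(df[, 2:(ncol(df) - 1), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num) | abs(num - round(num)) > 1e-9, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer count '", raw[bad[1, 1], bad[1, 2]], "' at OTU '",
         otuIds[bad[1, 1]], "', sample '", sampleIds[bad[1, 2]], "'")
  dimnames(num) <- list(otuIds, sampleIds)
  OtuExperiment(num, df[[ncol(df)]])
}

readBiomTable <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b)) # observations x samples
  om <- biomformat::observation_metadata(b)
  tax <- if (is.null(om)) rep("Unassigned", nrow(m))
  else if (is.data.frame(om))
    apply(om, 1, function(r) paste(r[nzchar(r) & !is.na(r)], collapse = "; "))
  else vapply(om, function(r) paste(unlist(r), collapse = "; "), "")
  OtuExperiment(m, as.character(tax))
}

#' Write an OTU table (and optional metadata) as TSV
#'
#' @param x an [OtuExperiment-class].
#' @param path output file.
#' @export
writeOtuTable <- function(x, path) {
  df <- data.frame(otu_id = rownames(x), counts(x), check.names = FALSE)
  df$taxonomy <- taxonomy(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample-metadata TSV
#'
#' Header: sample_id, sample_type, population, plant, age_days, weight_mg,
#' survived_15d, family_id; empty cells are absent values.
#'
#' @param path file path.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "sample_type")
  if (!all(need %in% colnames(df)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if ("survived_15d" %in% names(df))
    df$survived_15d <- as.logical(df$survived_15d)
  df
}

#' @rdname readSampleMetadata
#' @param metadata data.frame of sample metadata.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Remove OTUs matching taxonomy exclusion rules
#'
#' Drops OTU rows whose lineage matches any rule (chloroplast, mitochondria,
#' Wolbachia, unassigned, ...). The operation is idempotent.
#'
#' @param x an [OtuExperiment-class].
#' @param exclude list of [taxonRule()] objects and/or the string
#'   `"unassigned"`; OTUs matching any rule are removed. Samples are retained
#'   even if their counts drop to zero; OTU order is preserved.
#' @export
setMethod("filterTaxa", "OtuExperiment", function(x, exclude) {
  if (inherits(exclude, "taxonRule") || identical(exclude, "unassigned"))
    exclude <- list(exclude)
  parsed <- parseLineage(taxonomy(x))
  drop <- Reduce(`|`, lapply(exclude, matchesRule, parsed = parsed),
                 rep(FALSE, nrow(x)))
  if (all(drop)) stop("taxonomic filter removed every OTU")
  x[!drop, ]
})

#' Drop OTUs that never reach a relative-abundance threshold
#'
#' @param x an [OtuExperiment-class].
#' @param minRelAbund an OTU is retained iff its within-sample relative
#'   abundance reaches this fraction in at least one sample (default 1%).
#' @export
setMethod("filterRareOtus", "OtuExperiment", function(x, minRelAbund = 0.01) {
  stopifnot(minRelAbund >= 0, minRelAbund < 1)
  m <- counts(x)
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("sample(s) with zero total counts contribute no retention votes: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
  }
  use <- tot > 0
  if (!any(use)) stop("all samples have zero totals")
  rel <- sweep(m[, use, drop = FALSE], 2, tot[use], "/")
  keep <- apply(rel, 1, max) >= minRelAbund
  if (minRelAbund == 0) keep <- rep(TRUE, nrow(m))
  if (!any(keep)) stop("rare-OTU filter removed every OTU")
  x[keep, ]
})

#' Rarefy samples to a common sequencing depth
#'
#' @param x an [OtuExperiment-class].
#' @param depth target sequencing depth; samples with fewer than `depth`
#'   total counts are dropped (a total of exactly `depth` is retained
#'   unchanged) and recorded, retrievable with [droppedSamples()].
#' @param seed integer; each sample gets an independent RNG stream keyed by
#'   `(seed, sample_id)`, so removing one sample does not change the draws
#'   of the others.
#' @details Rarefaction is a uniform subsample *without replacement* of each
#'   sample's sequences, i.e. a multivariate hypergeometric draw.
#' @export
setMethod("rarefy", "OtuExperiment", function(x, depth, seed = 1L) {
  stopifnot(depth >= 1)
  m <- counts(x)
  tot <- colSums(m)
  keep <- tot >= depth
  if (!any(keep))
    stop("all samples have fewer than ", depth, " sequences")
  out <- m[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    out[, j] <- withSeed(stringSeed(seed, colnames(out)[j]),
                         rarefyVector(out[, j], depth))
  }
  res <- x[, keep]
  SummarizedExperiment::assay(res, "counts") <- out
  S4Vectors::metadata(res)$dropped_samples <- colnames(m)[!keep]
  validObject(res)
  res
})

# Multivariate hypergeometric draw via sequential rhyper: category i receives
# Hypergeometric(count_i, remaining counts, remaining depth).
rarefyVector <- function(cnt, depth) {
  if (sum(cnt) == depth) return(cnt)
  rem <- sum(cnt)
  left <- depth
  out <- numeric(length(cnt))
  for (i in seq_along(cnt)) {
    if (left == 0) break
    rem <- rem - cnt[i]
    if (rem == 0) { out[i] <- left; left <- 0; break }
    out[i] <- stats::rhyper(1, cnt[i], rem, left)
    left <- left - out[i]
  }
  out
}

#' Per-sample relative abundances
#'
#' @param x an [OtuExperiment-class].
#' @return samples x OTUs matrix of per-sample relative abundances (rows sum
#'   to 1), the orientation community-ecology functions expect.
#' @export
setMethod("relativeAbundance", "OtuExperiment", function(x) {
  m <- t(counts(x))
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  m / tot
})
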