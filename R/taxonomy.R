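#' Parse Greengenes-style taxonomy lineage strings
#'
#' Lineages look like `"k__Bacteria; p__Proteobacteria; c__...; o__...;
#' f__...; g__...; s__..."`. Rank prefixes must appear in canonical
#' kingdom-to-species order; trailing ranks may be missing or empty. An empty
#' string or `"Unassigned"` parses to an all-`NA` lineage.
#'
#' @param lineages character vector of lineage strings.
#' @return data.frame with one row per lineage: columns `kingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species` (NA where absent) and
#'   `raw` (the input).
#' @export
#' @examples
#' parseLineage("k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales")
parseLineage <- function(lineages) {
  prefixes <- c("k", "p", "c", "o", "f", "g", "s")
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  out <- matrix(NA_character_, length(lineages), length(ranks),
                dimnames = list(NULL, ranks))
  for (i in seq_along(lineages)) {
    raw <- lineages[i]
    if (is.na(raw) || !nzchar(trimws(raw)) ||
        tolower(trimws(raw)) == "unassigned") next
    parts <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    pos <- 0L
    for (p in parts) {
      if (!grepl("^[kpcofgs]__", p))
        stop("malformed lineage element '", p, "' in '", raw, "'")
      j <- match(substr(p, 1, 1), prefixes)
      if (j <= pos)
        stop("rank prefixes out of canonical order in '", raw, "'")
      pos <- j
      name <- substring(p, 4)
      if (nzchar(name)) out[i, j] <- name
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  df$raw <- as.character(lineages)
  df
}

#' Serialize parsed lineages back to strings
#'
#' Inverse of [parseLineage()] modulo whitespace: ranks present in the parsed
#' form are emitted as `prefix__Name` joined by `"; "`; empty trailing ranks
#' in the original are not restored.
#'
#' @param parsed data.frame as returned by [parseLineage()].
#' @return character vector of lineage strings.
#' @export
formatLineage <- function(parsed) {
  prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                family = "f", genus = "g", species = "s")
  apply(parsed[names(prefixes)], 1, function(r) {
    keep <- !is.na(r)
    if (!any(keep)) return("Unassigned")
    paste0(prefixes[keep], "__", r[keep], collapse = "; ")
  })
}

# An OTU counts as unassigned when its lineage is empty/"Unassigned" or
# carries no information beyond the kingdom rank.
isUnassignedLineage <- function(parsed) {
  below <- c("phylum", "class", "order", "family", "genus", "species")
  apply(parsed[below], 1, function(r) all(is.na(r)))
}

#' Taxonomy exclusion rule
#'
#' Builds a single match rule for [filterTaxa()]: an OTU matches when its
#' lineage has `name` (case-insensitive) at `rank`. An optional fallback rank
#' is consulted only when the primary rank is absent from the lineage, e.g.
#' [wolbachiaRule()] matches genus Wolbachia but falls back to order
#' Rickettsiales for genus-less lineages.
#'
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @param name taxon name to match.
#' @param fallbackRank,fallbackName optional secondary rule.
#' @return a rule object understood by [filterTaxa()].
#' @export
taxonRule <- function(rank, name, fallbackRank = NULL, fallbackName = NULL) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  rank <- match.arg(rank, ranks)
  if (!is.null(fallbackRank)) fallbackRank <- match.arg(fallbackRank, ranks)
  structure(list(rank = rank, name = name, fallbackRank = fallbackRank,
                 fallbackName = fallbackName), class = "taxonRule")
}

#' @rdname taxonRule
#' @export
wolbachiaRule <- function()
  taxonRule("genus", "Wolbachia", "order", "Rickettsiales")

#' Stock rule sets for the two filtering stages
#'
#' `organelleRules()` removes chloroplast (class) and mitochondrial (family)
#' 16S reads plus unassigned OTUs; `hostFilterRules()` additionally removes
#' Wolbachia, the intracellular endosymbiont that dominates whole-caterpillar
#' samples but is not part of the gut community.
#'
#' @return list of rules for [filterTaxa()].
#' @export
organelleRules <- function() {
  list(taxonRule("class", "Chloroplast"),
       taxonRule("family", "mitochondria"),
       "unassigned")
}

#' @rdname organelleRules
#' @export
hostFilterRules <- function() c(list(wolbachiaRule(), "unassigned"))

matchesRule <- function(parsed, rule) {
  if (identical(rule, "unassigned")) return(isUnassignedLineage(parsed))
  if (!inherits(rule, "taxonRule"))
    stop("exclusion rules must be taxonRule objects or \"unassigned\"")
  val <- parsed[[rule$rank]]
  hit <- !is.na(val) & tolower(val) == tolower(rule$name)
  if (!is.null(rule$fallbackRank)) {
    fb <- parsed[[rule$fallbackRank]]
    hit <- hit | (is.na(val) & !is.na(fb) &
                    tolower(fb) == tolower(rule$fallbackName))
  }
  hit
}
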