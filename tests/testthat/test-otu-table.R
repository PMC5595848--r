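test_that("taxonomy lineages parse and round-trip modulo whitespace", {
  raw <- c("k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales",
           "k__Bacteria;p__Proteobacteria;  c__Alphaproteobacteria",
           "Unassigned", "")
  p <- parseLineage(raw)
  expect_equal(p$order[1], "Lactobacillales")
  expect_equal(p$class[2], "Alphaproteobacteria")
  expect_true(all(is.na(p[3, c("kingdom", "genus")])))
  back <- formatLineage(p)
  norm <- function(x) gsub("\\s+", "", x)
  expect_equal(norm(back[1:2]), norm(raw[1:2]))
  expect_equal(back[3:4], c("Unassigned", "Unassigned"))
  # out-of-order prefixes are rejected
  expect_error(parseLineage("p__Firmicutes; k__Bacteria"), "canonical order")
})

test_that("TSV reader returns the right shape and validates its input", {
  oe <- readOtuTable(writeTsvFixture())
  expect_s4_class(oe, "OtuExperiment")
  expect_equal(dim(oe), c(4L, 3L)) # 4 OTUs, 3 samples
  expect_equal(unname(counts(oe)["otu2", "sampleB"]), 7)
  expect_equal(taxonomy(oe)[4], "Unassigned")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts1\ttaxonomy", "o1\t1\t2\tk__Bacteria"), dup)
  expect_error(readOtuTable(dup), "duplicate sample id.*s1")

  dupo <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ttaxonomy", "o1\t1\tk__Bacteria",
               "o1\t2\tk__Bacteria"), dupo)
  expect_error(readOtuTable(dupo), "duplicate OTU id.*o1")

  nonint <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2\ttaxonomy", "o1\t1\t2.5\tk__Bacteria"), nonint)
  expect_error(readOtuTable(nonint), "non-integer count '2.5'.*o1.*s2")
})

test_that("writer then reader is the identity on valid tables", {
  oe <- makeOtu(matrix(c(5, 0, 2, 3, 7, 1, 0, 1, 9), 3, 3))
  path <- tempfile(fileext = ".tsv")
  writeOtuTable(oe, path)
  back <- readOtuTable(path)
  expect_equal(counts(back), counts(oe))
  expect_equal(taxonomy(back), taxonomy(oe))
  expect_equal(dimnames(back), dimnames(oe))
})

test_that("metadata TSV round-trips with empty cells as NA", {
  md <- data.frame(sample_id = c("a", "b"),
                   sample_type = c("frass", "plant_epiphyte"),
                   population = c("BST", "HWR"), plant = c("Me", "Lu"),
                   age_days = c(15L, NA), weight_mg = c(6.1, NA),
                   survived_15d = c(TRUE, NA), family_id = c("f1", NA))
  path <- tempfile(fileext = ".tsv")
  writeSampleMetadata(md, path)
  back <- readSampleMetadata(path)
  expect_equal(back$age_days, c(15L, NA))
  expect_equal(back$survived_15d, c(TRUE, NA))
  expect_equal(back$weight_mg, md$weight_mg)
})

test_that("filterTaxa removes matching OTUs and nothing else", {
  tax <- c("k__Bacteria; p__Proteobacteria; o__Rickettsiales; g__Wolbachia",
           "k__Bacteria; p__Firmicutes; g__Lactobacillus",
           "k__Bacteria; p__Proteobacteria; g__Pseudomonas")
  oe <- makeOtu(matrix(1:9, 3, 3), taxonomy = tax)
  flt <- filterTaxa(oe, list(taxonRule("genus", "Wolbachia")))
  expect_equal(nrow(flt), 2L)
  expect_false(any(grepl("Wolbachia", taxonomy(flt))))
  # rule matching nothing is a no-op
  noop <- filterTaxa(oe, list(taxonRule("genus", "Nonexistent")))
  expect_equal(counts(noop), counts(oe))
  # removing everything is an error, not an empty table
  expect_error(filterTaxa(oe, list(taxonRule("kingdom", "Bacteria"))),
               "every OTU")
})

test_that("chloroplast/mitochondria/unassigned filter keeps the 5 bacterial OTUs", {
  tax <- c("k__Bacteria; p__Cyanobacteria; c__Chloroplast; o__Streptophyta",
           "k__Bacteria; p__Cyanobacteria; c__Chloroplast",
           "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; f__mitochondria",
           sprintf("k__Bacteria; p__Firmicutes; c__Bacilli; g__g%d", 1:5))
  oe <- makeOtu(matrix(1, 8, 2), taxonomy = tax)
  flt <- filterTaxa(oe, organelleRules())
  expect_equal(nrow(flt), 5L)
  # filtering is idempotent
  expect_equal(counts(filterTaxa(flt, organelleRules())), counts(flt))
})

test_that("Wolbachia rule falls back to Rickettsiales only without a genus", {
  tax <- c("k__Bacteria; p__Proteobacteria; o__Rickettsiales; g__Wolbachia",
           "k__Bacteria; p__Proteobacteria; o__Rickettsiales",
           "k__Bacteria; p__Proteobacteria; o__Rickettsiales; g__Ehrlichia")
  oe <- makeOtu(matrix(1, 3, 2), taxonomy = tax)
  flt <- filterTaxa(oe, list(wolbachiaRule()))
  # genus match and genus-less Rickettsiales go; named other genus stays
  expect_equal(rownames(flt), "otu03")
})

test_that("rare-OTU filter retains any OTU reaching the threshold somewhere", {
  # totals 200 each; otu1: 2% in sample 1 only; otu2: 0.5% everywhere
  cnt <- rbind(otu1 = c(4, 0, 0), otu2 = c(1, 1, 1),
               otu3 = c(195, 199, 199))
  oe <- makeOtu(cnt)
  flt <- filterRareOtus(oe, 0.01)
  expect_true("otu1" %in% rownames(flt))   # >= 1% in at least one sample
  expect_false("otu2" %in% rownames(flt))  # < 1% in all samples
  expect_equal(counts(filterRareOtus(oe, 0)), counts(oe)) # vacuous filter
  expect_equal(counts(filterRareOtus(flt, 0.01)), counts(flt)) # idempotent
  # zero-total samples warn but do not fail
  cnt0 <- cbind(cnt, c(0, 0, 0))
  colnames(cnt0) <- paste0("s", 1:4)
  expect_warning(filterRareOtus(makeOtu(cnt0), 0.01), "zero total")
})

test_that("rarefaction conserves depth, drops shallow samples, is seeded", {
  oe <- makeOtu(cbind(a = c(5, 5), b = c(2, 1), c = c(1000, 0)))
  r <- rarefy(oe, 4, seed = 11)
  expect_equal(droppedSamples(r), "b") # total 3 < 4
  expect_true(all(colSums(counts(r)) == 4))
  expect_true(all(counts(r) <= counts(oe)[, c("a", "c")]))
  # no mass can move to a zero category
  r500 <- rarefy(makeOtu(cbind(x = c(1000, 0))), 500, seed = 1)
  expect_equal(unname(counts(r500)[, 1]), c(500, 0))
  # a sample at exactly the depth is retained unchanged
  r4 <- rarefy(makeOtu(cbind(x = c(3, 1))), 4, seed = 1)
  expect_equal(unname(counts(r4)[, 1]), c(3, 1))
  # reproducible given seed
  expect_identical(counts(rarefy(oe, 4, seed = 3)),
                   counts(rarefy(oe, 4, seed = 3)))
  expect_error(rarefy(makeOtu(cbind(x = c(1, 1))), 10), "fewer than 10")
})

test_that("per-sample RNG streams make draws independent of other samples", {
  oe <- makeOtu(cbind(a = c(50, 30, 20), b = c(40, 40, 20), c = c(30, 30, 30)))
  full <- counts(rarefy(oe, 60, seed = 7))
  part <- counts(rarefy(oe[, c("a", "c")], 60, seed = 7))
  expect_identical(full[, c("a", "c")], part)
})

test_that("rarefied counts have the hypergeometric expectation", {
  cnt <- c(6, 3, 1); depth <- 5; N <- sum(cnt)
  oe <- makeOtu(matrix(cnt, ncol = 1, dimnames = list(NULL, "s")))
  draws <- vapply(seq_len(1000), function(s)
    counts(rarefy(oe, depth, seed = s))[, 1], numeric(3))
  m <- rowMeans(draws)
  expected <- depth * cnt / N
  # 3 standard errors of the mean under the hypergeometric variance
  se <- sqrt(depth * (cnt / N) * (1 - cnt / N) * (N - depth) / (N - 1) / 1000)
  expect_true(all(abs(m - expected) <= 3 * se + 1e-12))
})

test_that("relative abundance rows sum to one and zero rows are named", {
  oe <- makeOtu(cbind(s1 = c(5, 5, 0, 0), s2 = c(2, 2, 3, 3)))
  rel <- relativeAbundance(oe)
  expect_equal(unname(rel["s1", ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(rel["s2", ]), c(0.2, 0.2, 0.3, 0.3))
  expect_equal(unname(rowSums(rel)), c(1, 1))
  oe0 <- makeOtu(cbind(s1 = c(1, 1), bad = c(0, 0)))
  expect_error(relativeAbundance(oe0), "bad")
})

test_that("OtuExperiment validity catches bad inputs", {
  expect_error(OtuExperiment(matrix(-1, 1, 1, dimnames = list("o", "s")), "k__B"))
  expect_error(OtuExperiment(matrix(1.5, 1, 1, dimnames = list("o", "s")), "k__B"))
  expect_error(OtuExperiment(matrix(1, 2, 1, dimnames = list(c("o", "o"), "s")),
                             c("k__B", "k__B")))
  expect_error(OtuExperiment(matrix(1, 1, 1, dimnames = list("o", "s")),
                             character()), "taxonomy length")
})

test_that("BIOM-JSON tables read into the same container", {
  m <- matrix(c(5, 0, 2, 3, 7, 1), 3, 2,
              dimnames = list(paste0("o", 1:3), c("s1", "s2")))
  b <- biomformat::make_biom(m, observation_metadata = data.frame(
    r1 = rep("k__Bacteria", 3), r2 = c("p__A", "p__B", ""),
    row.names = rownames(m)))
  tf <- tempfile(fileext = ".biom")
  biomformat::write_biom(b, tf)
  oe <- readOtuTable(tf, format = "biom_json")
  expect_equal(unname(counts(oe)), unname(m))
  expect_equal(taxonomy(oe)[1], "k__Bacteria; p__A")
})
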