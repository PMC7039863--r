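test_that("verification keeps candidates closest to ratified enzymes", {
  ts <- makeSyntheticTrainingSet("DsyB", nPositives = 4, nNegatives = 3)
  degap <- function(x) gsub("[-.]", "", x)
  posSeq <- degap(as.character(ts@positives)[1])
  negLike <- mutateFamilySequence(familyReference("DmdA"), 0.1, seed = 3)
  genes <- data.frame(geneId = c("isPos", "isNeg"),
                      protein = c(posSeq, negLike), stringsAsFactors = FALSE)
  hits <- data.frame(geneId = c("isPos", "isNeg"), family = "DsyB",
                     bitScore = c(500, 400), eValue = 1e-30, verified = NA,
                     stringsAsFactors = FALSE)
  v <- verifyCandidates(hits, genes, list(DsyB = ts))
  expect_true(v$verified[v$geneId == "isPos"])
  expect_false(v$verified[v$geneId == "isNeg"])
})

test_that("verification ties are removed and multi-family hits deduplicated", {
  # a negative identical to a positive forces an exact score tie
  seqs <- c("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
  ts <- trainingSet("Tie", seqs[1], negatives = seqs[2])
  genes <- data.frame(geneId = "cand", protein = seqs[1],
                      stringsAsFactors = FALSE)
  hits <- data.frame(geneId = "cand", family = "Tie", bitScore = 100,
                     eValue = 1e-10, verified = NA, stringsAsFactors = FALSE)
  v <- verifyCandidates(hits, genes, list(Tie = ts))
  expect_false(v$verified)

  # gene hitting two families keeps only the higher-scoring one
  ts2 <- makeSyntheticTrainingSet("DsyB", nPositives = 3, nNegatives = 2)
  cand <- gsub("[-.]", "", as.character(ts2@positives)[1])
  genes2 <- data.frame(geneId = "g", protein = cand,
                       stringsAsFactors = FALSE)
  hits2 <- data.frame(geneId = "g", family = c("DsyB", "DmdA"),
                      bitScore = c(600, 300), eValue = 1e-40,
                      verified = NA, stringsAsFactors = FALSE)
  v2 <- verifyCandidates(hits2, genes2,
                         list(DsyB = ts2,
                              DmdA = makeSyntheticTrainingSet("DmdA")))
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$family, "DsyB")

  # family without negatives: cutoff-only acceptance with a warning
  tsNoNeg <- trainingSet("Bare", "ACDEFGHIKLMNPQRSTVWY")
  hits3 <- data.frame(geneId = "g", family = "Bare", bitScore = 10,
                      eValue = 1, verified = NA, stringsAsFactors = FALSE)
  genes3 <- data.frame(geneId = "g", protein = "ACDEFGHIKLMNPQRSTVWY",
                       stringsAsFactors = FALSE)
  expect_warning(v3 <- verifyCandidates(hits3, genes3, list(Bare = tsNoNeg)),
                 "cutoff-only")
  expect_true(v3$verified)
})

test_that("marker denominators respect the E-value cutoffs", {
  table <- data.frame(geneId = c("r1", "r2"), sampleId = "S",
                      abundance = c(0.02, 0.05), stringsAsFactors = FALSE)
  hits <- data.frame(geneId = c("r1", "r2"), family = "RecA",
                     bitScore = c(400, 200), eValue = c(1e-60, 1e-40),
                     verified = TRUE, stringsAsFactors = FALSE)
  # only the 1e-60 hit passes E <= 1e-50
  expect_equal(markerAbundance(table, hits, markerSpec("RecA"), "S"), 0.02)
  hitsWeak <- hits[2, ]
  expect_warning(
    expect_true(is.na(markerAbundance(table, hitsWeak,
                                      markerSpec("RecA"), "S"))),
    "undefined")
})

test_that("community fractions recover exact noise-free carriage", {
  fx <- exactCensusFixture(n = 100, k = 30)
  expect_equal(communityFraction(fx$table, fx$hits, "DsyB", "S01"), 30.0)
  # zero verified hits for another family with a valid denominator
  expect_equal(communityFraction(fx$table, fx$hits, "DmdA", "S01"), 0.0)
  # multi-copy family exceeding 100% is reported unclamped with a warning
  fx2 <- exactCensusFixture(n = 10, k = 10)
  extra <- fx2$hits[fx2$hits$family == "DsyB", ][1, ]
  extra$geneId <- "dup"
  tab2 <- rbind(fx2$table,
                data.frame(geneId = "dup", sampleId = "S01",
                           abundance = 0.5))
  expect_warning(
    frac <- communityFraction(tab2, rbind(fx2$hits, extra), "DsyB", "S01"),
    "unclamped")
  expect_gt(frac, 100)
})

test_that("census table assembles fractions and group means", {
  fx <- exactCensusFixture(n = 50, k = 10)
  # second sample with doubled counts: same fractions
  counts2 <- cbind(fx$counts, S02 = fx$counts[, 1] * 10L)
  tab <- computeAbundance(fx$genes, counts2)
  ct <- censusTable(c("S01", "S02"), tab, fx$hits,
                    groups = data.frame(sampleId = c("S01", "S02"),
                                        group = "sed"))
  fr <- censusFractions(ct)
  expect_equal(unname(fr["DsyB", ]), c(20, 20))
  expect_equal(unname(groupMeans(ct)["DsyB", "sed"]), 20)
  expect_error(censusTable("nope", tab, fx$hits), "unknown sample")

  # arithmetic mean over unequal samples
  tab3 <- rbind(fx$table,
                within(fx$table[fx$table$geneId %in%
                  fx$hits$geneId[fx$hits$family == "RecA"] |
                  fx$table$geneId %in% head(
                    fx$hits$geneId[fx$hits$family == "DsyB"], 5), ],
                  sampleId <- "S03"))
  ct3 <- censusTable(c("S01", "S03"), tab3, fx$hits,
                     groups = data.frame(sampleId = c("S01", "S03"),
                                         group = "g"))
  expect_equal(unname(censusFractions(ct3)["DsyB", ]), c(20, 10))
  expect_equal(unname(groupMeans(ct3)["DsyB", "g"]), 15)
})

test_that("fractions are invariant to count rescaling and gene length", {
  # scale invariance
  fx <- exactCensusFixture(n = 80, k = 24)
  tabScaled <- fx$table
  tabScaled$abundance <- tabScaled$abundance * 10
  f1 <- communityFraction(fx$table, fx$hits, "DsyB", "S01")
  f2 <- communityFraction(tabScaled, fx$hits, "DsyB", "S01")
  expect_equal(f1, f2, tolerance = 1e-12)

  # length robustness: family gene 3x longer than recA, counts exact
  # (proportional to length) -> normalization cancels
  n <- 40; k <- 10
  genomes <- sprintf("g%03d", seq_len(n))
  genes <- rbind(
    data.frame(geneId = paste0(genomes, ".recA"), family = "RecA",
               ntLength = 900L, stringsAsFactors = FALSE),
    data.frame(geneId = paste0(genomes[1:k], ".fam"), family = "DsyB",
               ntLength = 2700L, stringsAsFactors = FALSE))
  counts <- matrix(as.integer(genes$ntLength / 10), nrow(genes), 1,
                   dimnames = list(genes$geneId, "S01"))
  tab <- computeAbundance(genes, counts)
  hits <- data.frame(geneId = genes$geneId, family = genes$family,
                     bitScore = 1000, eValue = 0, verified = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(communityFraction(tab, hits, "DsyB", "S01"), 100 * k / n)
})

test_that("carriage estimates track abundance-weighted truth without bias", {
  # truths x seeds grid, modest sizes; errors measured against the
  # recorded community (cell-weighted) carriage
  tr <- makeSyntheticTaxonomy()
  errs <- c()
  for (truth in c(0.05, 0.30)) {
    for (seed in 1:5) {
      cm <- generateCommunity(100, c(DsyB = truth), tr,
                              backgroundGenes = 0L, seed = 1000 + seed)
      counts <- simulateCounts(cm, meanDepth = 20 * 100)
      tab <- computeAbundance(communityGenes(cm), counts)
      est <- communityFraction(tab, truthHits(cm), "DsyB", "S01")
      errs <- c(errs, est - 100 * communityTruth(cm)$DsyB$communityCarriage)
    }
  }
  expect_lt(mean(abs(errs)), 2)
  # no systematic sign bias (binomial two-sided on error signs)
  nPos <- sum(errs > 0)
  pval <- binom.test(nPos, length(errs))$p.value
  expect_gt(pval, 0.05)
})
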