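fixtureTree <- makeSyntheticTaxonomy(branching = c(phylum = 3, class = 2,
                                                   order = 2, family = 2,
                                                   genus = 2))

test_that("the synthetic taxonomy is a valid rooted tree", {
  expect_true(validObject(fixtureTree))
  expect_gte(nrow(taxNodes(fixtureTree)), 180)
  expect_gte(length(genusNodes(fixtureTree, "Bacteria")), 2)
  # round trip through the TSV format
  path <- tempfile(fileext = ".tsv")
  writeTaxonomy(fixtureTree, path)
  expect_equal(taxNodes(readTaxonomy(path)), taxNodes(fixtureTree))
})

test_that("LCA assignment handles single hits, siblings, and domains", {
  nd <- taxNodes(fixtureTree)
  genera <- nd$nodeId[nd$rank == "genus"]
  g1 <- genera[1]
  one <- data.frame(taxonId = g1, bitScore = 80)
  expect_equal(assignLca(one, fixtureTree), g1)

  # two sibling genera within the top-score band collapse to their family
  fam <- nd$parentId[nd$nodeId == g1]
  sibs <- nd$nodeId[nd$parentId == fam & nd$rank == "genus"]
  two <- data.frame(taxonId = sibs, bitScore = c(50, 49))
  expect_equal(assignLca(two, fixtureTree, topFraction = 0.10, minScore = 40), fam)
  # best-hit-only mode keeps the top genus
  expect_equal(assignLca(two, fixtureTree, minScore = 40, bestHitOnly = TRUE), sibs[1])

  # hits spanning both domains resolve to the root
  gB <- genusNodes(fixtureTree, "Bacteria")[1]
  gE <- genusNodes(fixtureTree, "Eukaryota")[1]
  both <- data.frame(taxonId = c(gB, gE), bitScore = c(60, 58))
  expect_equal(assignLca(both, fixtureTree), "root")

  # min-score filter and empty hit sets
  weak <- data.frame(taxonId = g1, bitScore = 20)
  expect_equal(assignLca(weak, fixtureTree, minScore = 50), "unassigned")
  expect_equal(assignLca(NULL, fixtureTree), "unassigned")
  expect_error(assignLca(data.frame(taxonId = "nope", bitScore = 90),
                         fixtureTree), "integrity")
})

test_that("LCA equals the root-path-intersection oracle on random hit sets", {
  nd <- taxNodes(fixtureTree)
  pool <- nd$nodeId[nd$rank %in% c("genus", "species", "family", "order")]
  for (seed in 1:100) {
    set.seed(seed)
    k <- sample(1:6, 1)
    taxa <- sample(pool, k, replace = TRUE)
    scores <- runif(k, 64, 70)  # all within the 10% band of the best
    hs <- data.frame(taxonId = taxa, bitScore = scores)
    expect_equal(assignLca(hs, fixtureTree),
                 oracleLca(taxa, fixtureTree),
                 label = paste("seed", seed))
  }
})

test_that("taxon abundance rolls up cumulatively and conserves totals", {
  tree <- fixtureTree
  gB <- genusNodes(tree, "Bacteria")[1:2]
  table <- data.frame(geneId = c("a", "b", "c", "d"), sampleId = "S",
                      abundance = c(0.01, 0.02, 0.04, 0.08),
                      stringsAsFactors = FALSE)
  asg <- c(a = gB[1], b = gB[1], c = gB[2], d = "unassigned")
  ta <- taxonAbundance(asg, table, "S", tree)
  expect_equal(unname(ta$abundance[gB[1]]), 0.03)
  expect_equal(ta$unassigned, 0.08)
  # rollup monotone along the lineage of gB[1]
  lin <- sulfurCensus:::.lineage(tree, gB[1])
  vals <- ta$abundance[lin]
  expect_true(all(diff(vals) <= 1e-12))
  # conservation: domain totals + unassigned = table total
  domTotal <- sum(ta$abundance[c("Bacteria", "Eukaryota")], na.rm = TRUE)
  expect_equal(domTotal + ta$unassigned, sum(table$abundance),
               tolerance = 1e-9)

  # all genes unassigned
  ta0 <- taxonAbundance(c(a = "unassigned", b = "unassigned",
                          c = "unassigned", d = "unassigned"), table, "S",
                        tree)
  expect_equal(length(ta0$abundance), 0L)
  expect_equal(ta0$unassigned, sum(table$abundance))
})

test_that("genus ranking of family carriers follows abundance", {
  tree <- fixtureTree
  gB <- genusNodes(tree, "Bacteria")[1:2]
  verified <- data.frame(geneId = c("x", "y"), family = "DsyB",
                         bitScore = 500, eValue = 0, verified = TRUE,
                         stringsAsFactors = FALSE)
  table <- data.frame(geneId = c("x", "y"), sampleId = "S",
                      abundance = c(0.02, 0.01), stringsAsFactors = FALSE)
  asg <- c(x = gB[2], y = gB[1])
  rk <- taxaWithGene("DsyB", verified, asg, table, "S", tree)
  expect_equal(rk$taxonId, c(gB[2], gB[1]))
  expect_equal(rk$abundance, c(0.02, 0.01))
  expect_true(all(rk$rank == "genus"))
})

test_that("planted carriers are attributed to their true genera", {
  tree <- makeSyntheticTaxonomy()
  cm <- generateCommunity(16, c(DsyB = 0.5), tree, abundanceSigma = 0.5,
                          backgroundGenes = 0L, seed = 31)
  refDB <- makeSyntheticReferenceDB(tree, "DsyB", seed = 31)
  prot <- communityProteins(cm, referenceDB = refDB)
  genes <- communityGenes(cm)
  genes$protein <- unname(prot[genes$geneId])
  fam <- genes[genes$family == "DsyB", ]
  hitsets <- searchReference(fam, refDB$proteins, refDB$mapping,
                             minScore = 50)
  asg <- vapply(hitsets, assignLca, character(1), tree = tree)
  truthGenus <- setNames(communityTruth(cm)$DsyB$carriers$taxonId,
                         communityTruth(cm)$DsyB$carriers$genomeId)
  for (i in seq_len(nrow(fam))) {
    got <- asg[[fam$geneId[i]]]
    want <- truthGenus[[fam$genomeId[i]]]
    # exact genus or an ancestor on its lineage (never a wrong genus)
    expect_true(got %in% sulfurCensus:::.lineage(tree, want),
                label = paste(fam$geneId[i], got, want))
  }
  # ranking at exact abundances matches the truth's per-genus totals
  tab <- data.frame(geneId = fam$geneId, sampleId = "S",
                    abundance = communityGenomes(cm)$relAbundance[
                      match(fam$genomeId, communityGenomes(cm)$genomeId)],
                    stringsAsFactors = FALSE)
  verified <- data.frame(geneId = fam$geneId, family = "DsyB",
                         bitScore = 500, eValue = 0, verified = TRUE,
                         stringsAsFactors = FALSE)
  rk <- taxaWithGene("DsyB", verified, asg, tab, "S", tree)
  truthTotals <- tapply(tab$abundance, truthGenus[fam$genomeId], sum)
  genusRows <- rk[rk$rank == "genus", ]
  for (i in seq_len(nrow(genusRows)))
    expect_equal(genusRows$abundance[i],
                 unname(truthTotals[genusRows$taxonId[i]]))
})
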