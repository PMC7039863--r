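test_that("profile construction follows the majority-occupancy rule", {
  # three identical ungapped sequences: every column is a match column,
  # emissions peak on the observed residue
  s <- paste(rep("ACDEFGHIKL", 4), collapse = "")
  p <- buildProfile(trainingSet("T", rep(s, 3)))
  expect_equal(profileLength(p), 40L)
  top <- apply(p@matchEmissions, 1, function(r) names(r)[which.max(r)])
  expect_equal(paste(top, collapse = ""), s)

  # a 60%-gapped column is not a match column
  aln <- c("AC-DE", "A--DE", "AC-DE", "A-GDE", "ACGDE")  # col 3 gapped 3/5
  p2 <- buildProfile(trainingSet("T", aln))
  expect_equal(profileLength(p2), 4L)

  # single-sequence degenerate alignment
  p3 <- buildProfile(trainingSet("T", "ACDE"))
  expect_equal(profileLength(p3), 4L)
  expect_gt(p3@matchEmissions[1, "A"], max(p3@matchEmissions[1, -1]))

  expect_error(trainingSet("T", character(0)), "missing training")
  expect_error(trainingSet("T", c("ACDE", "ACD")), "ragged")
})

test_that("probability bundles are normalized after build and calibration", {
  ts <- makeSyntheticTrainingSet("DsyB", nPositives = 4, nNegatives = 2)
  p <- buildProfile(ts)
  p <- calibrateEvalue(p, decoyCount = 100, decoyLength = 60, seed = 7)
  tol <- 1e-9
  expect_true(all(abs(rowSums(p@matchEmissions) - 1) < tol))
  expect_lt(abs(sum(p@background) - 1), tol)
  tr <- p@transitions
  expect_true(all(abs(tr$mm + tr$mi + tr$md - 1) < tol))
  expect_true(all(abs(tr$im + tr$ii - 1) < tol))
  expect_true(all(abs(tr$dm + tr$dd - 1) < tol))
})

test_that("dynamic-programming score equals exhaustive path enumeration", {
  cases <- 0L
  for (L in 1:3) for (n in 1:3) for (rep in 1:8) {
    seed <- 1000L * L + 100L * n + rep
    p <- makeRandomToyProfile(L, seed)
    set.seed(seed + 5)
    q <- paste(sample(AA, n, replace = TRUE), collapse = "")
    expect_equal(scoreSequence(p, q), bruteForceProfileScore(p, q),
                 tolerance = 1e-12,
                 label = sprintf("L=%d n=%d rep=%d", L, n, rep))
    cases <- cases + 1L
  }
  expect_gte(cases, 72L)
})

test_that("self-sequence scores dominate mutants and shuffles", {
  s <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")
  p <- buildProfile(trainingSet("T", s))
  self <- scoreSequence(p, s)
  set.seed(11)
  for (i in 1:20) {
    chars <- strsplit(s, "")[[1]]
    pos <- sample(length(chars), 1)
    chars[pos] <- sample(setdiff(AA, chars[pos]), 1)
    expect_gte(self, scoreSequence(p, paste(chars, collapse = "")))
  }
  for (i in 1:20) {
    shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_lte(scoreSequence(p, shuf), self)
  }
})

test_that("query alphabet handling: empty, invalid, ambiguity", {
  p <- buildProfile(trainingSet("T", "ACDE"))
  expect_error(scoreSequence(p, ""), "empty")
  expect_error(scoreSequence(p, "AC-E"), "alphabet")
  expect_error(scoreSequence(p, "ACBE"), "alphabet")
  # flanking X scores as background and cannot raise a full match
  expect_equal(scoreSequence(p, "XACDEX"), scoreSequence(p, "ACDE"))
})

test_that("E-value calibration is seeded, monotone, and recovers Gumbel", {
  ts <- makeSyntheticTrainingSet("DmdA", nPositives = 3, nNegatives = 0)
  p <- buildProfile(ts)
  p1 <- calibrateEvalue(p, decoyCount = 150, decoyLength = 50, seed = 42)
  p2 <- calibrateEvalue(p, decoyCount = 150, decoyLength = 50, seed = 42)
  expect_identical(evdParams(p1), evdParams(p2))
  expect_error(calibrateEvalue(p, decoyCount = 50), "underpowered")

  # strictly decreasing E-value in score
  s <- seq(0, 100, by = 5)
  ev <- evalueFromScore(p1, s, 1000)
  expect_true(all(diff(ev) < 0))

  # parameter recovery on samples drawn from a known Gumbel
  lambda <- 0.67; mu <- 12
  set.seed(99)
  x <- mu - log(-log(runif(10000))) / lambda
  fit <- sulfurCensus:::.fitGumbel(x)
  expect_lt(abs(fit[["lambda"]] - lambda) / lambda, 0.10)
  expect_lt(abs(fit[["mu"]] - mu) / mu, 0.10)
})

test_that("family cutoffs sit between positives and negatives", {
  ts <- makeSyntheticTrainingSet("DsyB", nPositives = 5, nNegatives = 4)
  p <- deriveFamilyCutoff(buildProfile(ts), ts)
  degap <- function(x) gsub("[-.]", "", x)
  loo <- vapply(seq_len(5), function(i) {
    sub <- buildProfile(trainingSet("DsyB",
      as.character(ts@positives)[-i]))
    scoreSequence(sub, degap(as.character(ts@positives)[i]))
  }, numeric(1))
  negs <- vapply(as.character(ts@negatives),
                 function(x) scoreSequence(p, x), numeric(1))
  expect_equal(scoreCutoff(p), (min(loo) + max(negs)) / 2)
  expect_true(all(loo > scoreCutoff(p)))
  expect_true(all(negs < scoreCutoff(p)))

  # margin rule without negatives
  ts0 <- trainingSet("DsyB", as.character(ts@positives))
  p0 <- deriveFamilyCutoff(buildProfile(ts0), ts0, margin = 10)
  expect_equal(scoreCutoff(p0), min(loo) - 10)

  # non-separable training: conservative cutoff plus warning
  tsBad <- trainingSet("X", c("ACDEFGHIKL", "ACDEFGHIKL"),
                       negatives = "ACDEFGHIKL")
  expect_warning(pb <- deriveFamilyCutoff(buildProfile(tsBad), tsBad),
                 "not separable")
  looBad <- scoreSequence(buildProfile(trainingSet("X", "ACDEFGHIKL")),
                          "ACDEFGHIKL")
  expect_equal(scoreCutoff(pb), looBad)
})

test_that("catalog search finds planted homologs and nothing else", {
  ts <- makeSyntheticTrainingSet("DsyB")
  p <- calibrateEvalue(deriveFamilyCutoff(buildProfile(ts), ts),
                       decoyCount = 200, decoyLength = 100, seed = 3)
  planted <- mutateFamilySequence(familyReference("DsyB"), 0.3, seed = 21)
  set.seed(22)
  chars <- strsplit(planted, "")[[1]]
  decoys <- vapply(1:99, function(i)
    paste(sample(chars), collapse = ""), character(1))
  genes <- data.frame(
    geneId = c("planted", sprintf("decoy%02d", 1:99)),
    protein = c(planted, decoys), stringsAsFactors = FALSE)
  hits <- searchCatalog(list(p), genes)
  expect_equal(hits$geneId, "planted")
  expect_equal(hits$family, "DsyB")

  # training positives are self-detected above the leave-one-out cutoff
  posGenes <- data.frame(
    geneId = sprintf("pos%d", seq_along(ts@positives)),
    protein = gsub("[-.]", "", as.character(ts@positives)),
    stringsAsFactors = FALSE)
  selfHits <- searchCatalog(list(p), posGenes)
  expect_setequal(selfHits$geneId, posGenes$geneId)

  expect_equal(nrow(searchCatalog(list(p), genes[0, ])), 0L)
  expect_error(searchCatalog(list(buildProfile(ts)), genes),
               "calibration missing")
})

test_that("profile text serialization round-trips to 12 significant digits", {
  ts <- makeSyntheticTrainingSet("MddA", nPositives = 4, nNegatives = 2)
  p <- calibrateEvalue(deriveFamilyCutoff(buildProfile(ts), ts),
                       decoyCount = 120, decoyLength = 80, seed = 5)
  path <- tempfile(fileext = ".prof")
  writeProfile(p, path)
  p2 <- readProfile(path)
  expect_equal(p2@matchEmissions, p@matchEmissions, tolerance = 1e-11)
  expect_equal(p2@transitions, p@transitions, tolerance = 1e-11)
  expect_equal(scoreCutoff(p2), scoreCutoff(p), tolerance = 1e-11)
  expect_equal(evdParams(p2), evdParams(p), tolerance = 1e-11)
  expect_equal(scoreSequence(p2, "ACDEFGHIKLMNPQRSTVWY"),
               scoreSequence(p, "ACDEFGHIKLMNPQRSTVWY"), tolerance = 1e-9)
})
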