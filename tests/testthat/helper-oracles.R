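# Independent oracles and small fixture builders shared across tests.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ---- brute-force profile alignment oracle -------------------------------
# Enumerates every legal local state path (start and end in a match state,
# contiguous query substring, match/insert/delete moves) and returns the
# maximum log2-odds score.  Only feasible for tiny models/queries; used to
# verify the dynamic-programming scorer exactly.
bruteForceProfileScore <- function(profile, query) {
  E <- profile@matchEmissions
  bg <- profile@background
  lom <- log2(sweep(E, 2, bg, "/"))
  tr <- lapply(profile@transitions, log2)
  L <- nrow(E)
  q <- match(strsplit(query, "", fixed = TRUE)[[1]], AA)
  n <- length(q)
  best <- -Inf

  rec <- function(type, j, i, sc) {
    if (type == "M") best <<- max(best, sc)
    if (type == "M" && j <= L - 1) {
      if (i + 1 <= n)
        rec("M", j + 1, i + 1, sc + tr$mm[j] + lom[j + 1, q[i + 1]])
      if (i + 1 <= n)
        rec("I", j, i + 1, sc + tr$mi[j])
      rec("D", j + 1, i, sc + tr$md[j])
    }
    if (type == "I") {
      if (i + 1 <= n)
        rec("M", j + 1, i + 1, sc + tr$im[j] + lom[j + 1, q[i + 1]])
      if (i + 1 <= n)
        rec("I", j, i + 1, sc + tr$ii[j])
    }
    if (type == "D" && j <= L - 1) {
      if (i + 1 <= n)
        rec("M", j + 1, i + 1, sc + tr$dm[j] + lom[j + 1, q[i + 1]])
      rec("D", j + 1, i, sc + tr$dd[j])
    }
  }
  for (p in seq_len(n))
    for (j0 in seq_len(L))
      rec("M", j0, p, lom[j0, q[p]])
  best
}

# random toy ProfileModel with normalized emissions/transitions
makeRandomToyProfile <- function(L, seed) {
  set.seed(seed)
  E <- matrix(rgamma(L * 20, 0.8), L, 20)
  E <- E / rowSums(E)
  colnames(E) <- AA
  bg <- rgamma(20, 2)
  bg <- bg / sum(bg)
  names(bg) <- AA
  rnd3 <- function() { x <- rgamma(3, 1); x / sum(x) }
  rnd2 <- function() { x <- rgamma(2, 1); x / sum(x) }
  if (L > 1) {
    m <- replicate(L - 1, rnd3())
    i2 <- replicate(L - 1, rnd2())
    d2 <- replicate(L - 1, rnd2())
    tr <- list(mm = m[1, ], mi = m[2, ], md = m[3, ],
               im = i2[1, ], ii = i2[2, ], dm = d2[1, ], dd = d2[2, ])
  } else {
    tr <- list(mm = numeric(0), mi = numeric(0), md = numeric(0),
               im = numeric(0), ii = numeric(0), dm = numeric(0),
               dd = numeric(0))
  }
  new("ProfileModel", family = "toy", matchEmissions = E, transitions = tr,
      background = bg, pseudocountWeight = 1, scoreCutoff = NA_real_,
      evdLambda = NA_real_, evdMu = NA_real_, decoyCount = 0L)
}

# ---- brute-force greedy clustering oracle -------------------------------
# Same greedy contract as clusterGenes but written independently: no
# prescreen, its own identity/coverage computation via Biostrings.
oracleClusterGenes <- function(genes, identity = 0.95, coverage = 0.90) {
  idcov <- function(a, b) {
    if (nchar(a) <= nchar(b)) { p <- a; s <- b } else { p <- b; s <- a }
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(p), subject = Biostrings::AAString(s),
      type = "global-local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    w <- nchar(as.character(Biostrings::alignedPattern(aln)))
    c(nm / w, (nm + nmm) / nchar(p))
  }
  ord <- order(-genes$ntLength, genes$geneId)
  g <- genes[ord, , drop = FALSE]
  repRows <- integer(0)
  assign <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    placed <- FALSE
    for (j in repRows) {
      ic <- idcov(g$protein[i], g$protein[j])
      if (ic[1] >= identity && ic[2] >= coverage) {
        assign[i] <- g$geneId[j]; placed <- TRUE; break
      }
    }
    if (!placed) { repRows <- c(repRows, i); assign[i] <- g$geneId[i] }
  }
  out <- data.frame(geneId = g$geneId, representativeId = assign,
                    stringsAsFactors = FALSE)
  out[match(genes$geneId, out$geneId), , drop = FALSE]
}

# ---- root-path-intersection LCA oracle ----------------------------------
oracleLca <- function(taxa, tree) {
  nodes <- taxNodes(tree)
  parent <- setNames(nodes$parentId, nodes$nodeId)
  rootPath <- function(x) {
    path <- x
    while (x != taxRoot(tree)) { x <- parent[[x]]; path <- c(x, path) }
    path
  }
  paths <- lapply(unique(as.character(taxa)), rootPath)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# small fixed community for census tests: n equal-abundance bacterial
# genomes, k carrying one family gene, all with one recA, exact counts
exactCensusFixture <- function(n = 100, k = 30, family = "DsyB",
                               geneLen = 1200L, readsPerGene = 100L) {
  genomes <- sprintf("g%03d", seq_len(n))
  genes <- rbind(
    data.frame(geneId = paste0(genomes, ".recA"), family = "RecA",
               ntLength = geneLen, stringsAsFactors = FALSE),
    data.frame(geneId = paste0(genomes[seq_len(k)], ".fam"), family = family,
               ntLength = geneLen, stringsAsFactors = FALSE))
  counts <- matrix(readsPerGene, nrow(genes), 1,
                   dimnames = list(genes$geneId, "S01"))
  table <- computeAbundance(genes, counts)
  hits <- data.frame(geneId = genes$geneId, family = genes$family,
                     bitScore = 1000, eValue = 0, verified = TRUE,
                     stringsAsFactors = FALSE)
  list(genes = genes, counts = counts, table = table, hits = hits)
}
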