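#' @include AllClasses.R census.R
NULL

.pkgCache <- new.env(parent = emptyenv())

# BLOSUM62-biased substitution distribution: P(b | a) ~ bg(b) * 2^(S[a,b]/2)
# for b != a.  Rows original residue, columns replacement probability.
.substBias <- function() {
  if (!is.null(.pkgCache$substBias)) return(.pkgCache$substBias)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[AA20, AA20]
  bg <- aminoAcidBackground()
  W <- sweep(2^(S / 2), 2, bg, "*")
  diag(W) <- 0
  W <- W / rowSums(W)
  .pkgCache$substBias <- W
  W
}

# per-family reference protein lengths (residues); default 320
.FAMILY_AA_LENGTH <- c(
  RecA = 353, BetaActin = 375, DsyB = 340, DSYB = 395, DmdA = 365,
  DddP = 430, DddQ = 300, DddL = 240, MddA = 250, Alma1 = 380,
  DmdB = 330, MmtN = 280, DmoA = 420, Tmm = 450)

#' Deterministic reference protein for a gene family
#'
#' A seeded random protein of the family's characteristic length, used as
#' the ratified-enzyme stand-in from which training positives, planted
#' homologs and per-genus database variants are derived.  All sequences
#' produced from it are synthetic.
#'
#' @param family Family name.
#' @param length Residue length (default from an internal per-family
#'   table, 320 otherwise).
#' @param seed Base seed (default 20200218).
#' @return Protein string.
#' @export
familyReference <- function(family, length = NULL, seed = 20200218L) {
  if (is.null(length)) {
    length <- .FAMILY_AA_LENGTH[[family]]
    if (is.null(length) || is.na(length)) length <- 320L
  }
  randomProtein(length, deriveSeed(seed, paste0("ref:", family)))
}

#' Mutate a protein at a controlled divergence
#'
#' Substitutes exactly \code{round(divergence * length)} positions (chosen
#' without replacement); replacement residues are drawn from a
#' BLOSUM62-biased substitution distribution, so mutants remain detectable
#' homologs.  No indels are introduced unless \code{indelRate > 0}, in
#' which case short deletions are additionally applied (sequences then
#' change length).
#'
#' @param reference Protein string.
#' @param divergence Fraction of positions substituted, in [0, 0.6].
#' @param seed RNG seed.
#' @param indelRate Optional per-site deletion probability (default 0).
#' @return Mutated protein string.
#' @export
#' @examples
#' mutateFamilySequence("ACDEFGHIKL", 0.3, seed = 1)
mutateFamilySequence <- function(reference, divergence, seed,
                                 indelRate = 0) {
  if (divergence < 0 || divergence > 0.6)
    stop("divergence outside the validated range [0, 0.6]")
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  L <- length(chars)
  k <- round(divergence * L)
  W <- .substBias()
  withSeed(seed, {
    if (k > 0) {
      pos <- sample.int(L, k)
      for (p in pos) {
        a <- chars[p]
        if (a %in% AA20) chars[p] <- sample(AA20, 1, prob = W[a, ])
      }
    }
    if (indelRate > 0) {
      keep <- runif(length(chars)) >= indelRate
      chars <- chars[keep]
    }
  })
  paste(chars, collapse = "")
}

#' Synthetic training set for one family
#'
#' Positives are independent mutants of the family reference at
#' \code{posDivergence} (ungapped, hence trivially aligned); negatives are
#' mutants of other families' references (different function, similar
#' composition).
#'
#' @param family Family name.
#' @param nPositives,nNegatives Counts (defaults 8 and 6).
#' @param posDivergence Divergence of positives from the reference
#'   (default 0.15).
#' @param negFamilies Families supplying negatives (default: other bundled
#'   families).
#' @param seed Base seed.
#' @return A \linkS4class{TrainingSet}.
#' @export
makeSyntheticTrainingSet <- function(family, nPositives = 8L,
                                     nNegatives = 6L, posDivergence = 0.15,
                                     negFamilies = NULL,
                                     seed = 20200218L) {
  ref <- familyReference(family, seed = seed)
  pos <- vapply(seq_len(nPositives), function(i)
    mutateFamilySequence(ref, posDivergence,
                         deriveSeed(seed, sprintf("pos:%s:%d", family, i))),
    character(1))
  names(pos) <- sprintf("%s_pos%02d", family, seq_len(nPositives))
  if (is.null(negFamilies))
    negFamilies <- setdiff(c("DsyB", "DmdA", "DddP", "MddA", "Alma1",
                             "RecA", "BetaActin"), family)
  neg <- character(0)
  if (nNegatives > 0L) {
    nf <- rep_len(negFamilies, nNegatives)
    neg <- vapply(seq_len(nNegatives), function(i)
      mutateFamilySequence(familyReference(nf[i], seed = seed), posDivergence,
                           deriveSeed(seed, sprintf("neg:%s:%d", family, i))),
      character(1))
    names(neg) <- sprintf("%s_neg%02d_%s", family, seq_len(nNegatives), nf)
  }
  trainingSet(family, pos, neg)
}

#' Bundled synthetic families
#'
#' Training sets for a standard bundle of DMSP-cycling families plus the
#' two single-copy markers, generated deterministically from the package
#' seed.
#'
#' @param families Families to include.
#' @param ... Passed to \code{\link{makeSyntheticTrainingSet}}.
#' @return Named list of \linkS4class{TrainingSet}s.
#' @export
syntheticFamilySet <- function(families = c("DsyB", "DmdA", "DddP", "MddA",
                                            "Alma1", "RecA", "BetaActin"),
                               ...) {
  setNames(lapply(families, makeSyntheticTrainingSet, ...), families)
}

#' Build calibrated profiles for a set of training sets
#'
#' Convenience wrapper: profile construction, family cutoff derivation and
#' Gumbel E-value calibration in one call.
#'
#' @param training Named list of \linkS4class{TrainingSet}s.
#' @param pseudocountWeight Emission pseudocount mass (default 1).
#' @param decoyCount,decoyLength,seed Calibration settings.
#' @return Named list of calibrated \linkS4class{ProfileModel}s.
#' @export
buildCalibratedProfiles <- function(training, pseudocountWeight = 1,
                                    decoyCount = 1000L, decoyLength = 150L,
                                    seed = 20200218L) {
  lapply(training, function(ts) {
    p <- buildProfile(ts, pseudocountWeight)
    p <- deriveFamilyCutoff(p, ts)
    calibrateEvalue(p, decoyCount, decoyLength, seed)
  })
}

#' Synthetic taxonomy tree
#'
#' A rooted taxonomy with the standard ranks and a fixed branching factor
#' per rank under each domain; node ids encode the lineage so trees are
#' fully deterministic.
#'
#' @param branching Named integer vector: children per node at each of
#'   \code{phylum, class, order, family, genus}.
#' @param domains Domains to include.
#' @return A \linkS4class{TaxonomyTree}.
#' @export
#' @examples
#' tr <- makeSyntheticTaxonomy()
#' nrow(taxNodes(tr))
makeSyntheticTaxonomy <- function(branching = c(phylum = 2, class = 2,
                                                order = 2, family = 3,
                                                genus = 2),
                                  domains = c("Bacteria", "Eukaryota")) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  stopifnot(all(ranks %in% names(branching)))
  rows <- list(data.frame(nodeId = "root", parentId = "root",
                          rank = "root", name = "root",
                          stringsAsFactors = FALSE))
  for (d in domains) {
    rows[[length(rows) + 1L]] <- data.frame(
      nodeId = d, parentId = "root", rank = "domain", name = d,
      stringsAsFactors = FALSE)
    parents <- d
    for (r in ranks) {
      kids <- unlist(lapply(parents, function(p)
        paste0(p, ".", substr(r, 1, 1), seq_len(branching[[r]]))))
      par <- rep(parents, each = branching[[r]])
      rows[[length(rows) + 1L]] <- data.frame(
        nodeId = kids, parentId = par, rank = r, name = kids,
        stringsAsFactors = FALSE)
      parents <- kids
    }
  }
  taxonomyTree(do.call(rbind, rows))
}

#' Genus-rank nodes of a domain
#'
#' @param tree A \linkS4class{TaxonomyTree}.
#' @param domain Domain name.
#' @return Character vector of genus node ids.
#' @export
genusNodes <- function(tree, domain) {
  nd <- taxNodes(tree)
  genera <- nd$nodeId[nd$rank == "genus"]
  genera[vapply(genera, function(g) domain %in% .lineage(tree, g),
                logical(1))]
}

#' Generate a synthetic community with known ground truth
#'
#' Genomes receive lognormal relative abundances; every bacterial genome
#' carries exactly one recA and every eukaryotic genome one beta-actin;
#' each requested family is planted into exactly
#' \code{round(carriage * nDomainGenomes)} genomes (deterministic
#' planting, carriers chosen by seeded shuffle); remaining genes are
#' background.  The recorded truth holds both the genome-level carriage
#' and the abundance-weighted community carriage (the quantity that
#' marker-gene normalization estimates).
#'
#' @param nGenomes Total genomes (>= 10).
#' @param carriage data.frame \code{family, carriage} (optional
#'   \code{copies}, default 1), or a named numeric vector of carriage
#'   fractions.
#' @param taxonomy A \linkS4class{TaxonomyTree} with at least 2 genera per
#'   domain used.
#' @param abundanceSigma Lognormal shape of relative abundances (0 =
#'   uniform); default 1.
#' @param propEukaryote Fraction of genomes that are eukaryotic (default:
#'   0.25 when a eukaryotic family is requested, else 0).
#' @param backgroundGenes Background genes per genome (default 3).
#' @param lengthModel Named vector \code{meanlog, sdlog} of the background
#'   gene residue-length distribution (default log(300), 0.35).
#' @param seed Base seed; all substreams derive from it.
#' @return A \linkS4class{SyntheticCommunity}.
#' @export
#' @examples
#' tr <- makeSyntheticTaxonomy()
#' cm <- generateCommunity(20, c(DsyB = 0.3), tr, seed = 1)
#' communityTruth(cm)$DsyB$genomeCarriage
generateCommunity <- function(nGenomes, carriage, taxonomy,
                              abundanceSigma = 1, propEukaryote = NULL,
                              backgroundGenes = 3L,
                              lengthModel = c(meanlog = log(300),
                                              sdlog = 0.35),
                              seed = 20200218L) {
  if (nGenomes < 10L) stop("nGenomes must be >= 10")
  if (is.numeric(carriage) && !is.data.frame(carriage))
    carriage <- data.frame(family = names(carriage),
                           carriage = as.numeric(carriage),
                           stringsAsFactors = FALSE)
  if (!"copies" %in% colnames(carriage)) carriage$copies <- 1L
  stopifnot(all(carriage$carriage >= 0), all(carriage$carriage <= 1),
            all(carriage$copies >= 1))
  fd <- familyDomains()
  carriage$domain <- fd$domain[match(carriage$family, fd$family)]
  if (anyNA(carriage$domain))
    stop("unknown family: ",
         paste(carriage$family[is.na(carriage$domain)], collapse = ", "))
  if (is.null(propEukaryote))
    propEukaryote <- if (any(carriage$domain == "Eukaryota")) 0.25 else 0
  nEuk <- round(propEukaryote * nGenomes)
  nBact <- nGenomes - nEuk
  domains <- c(rep("Bacteria", nBact), rep("Eukaryota", nEuk))
  usedDomains <- unique(domains)
  for (d in usedDomains)
    if (length(genusNodes(taxonomy, d)) < 2L)
      stop("taxonomy needs >= 2 genera in domain ", d)

  genomeId <- sprintf("g%04d", seq_len(nGenomes))
  taxa <- withSeed(deriveSeed(seed, "community:taxa"), {
    vapply(domains, function(d)
      sample(genusNodes(taxonomy, d), 1), character(1))
  })
  relAb <- if (abundanceSigma == 0) rep(1, nGenomes) else
    withSeed(deriveSeed(seed, "community:abundance"),
             rlnorm(nGenomes, 0, abundanceSigma))
  relAb <- relAb / sum(relAb)
  genomes <- data.frame(genomeId = genomeId, domain = domains,
                        taxonId = unname(taxa), relAbundance = relAb,
                        stringsAsFactors = FALSE)

  genes <- list()
  addGene <- function(genome, family, aaLen, idx = 1L) {
    data.frame(geneId = sprintf("%s.%s.%d", genome, family, idx),
               genomeId = genome, family = family,
               ntLength = 3L * as.integer(aaLen), stringsAsFactors = FALSE)
  }
  # single-copy markers
  for (i in seq_len(nGenomes)) {
    m <- if (domains[i] == "Bacteria") "RecA" else "BetaActin"
    genes[[length(genes) + 1L]] <-
      addGene(genomeId[i], m, nchar(familyReference(m)))
  }
  # planted family genes + truth
  truth <- list()
  for (r in seq_len(nrow(carriage))) {
    fam <- carriage$family[r]
    dom <- carriage$domain[r]
    domIdx <- which(domains == dom)
    k <- round(carriage$carriage[r] * length(domIdx))
    if (k == 0L && carriage$carriage[r] > 0) {
      warning("carriage for ", fam, " rounds to 0 genomes; family absent")
    }
    carrierIdx <- if (k > 0L)
      withSeed(deriveSeed(seed, paste0("plant:", fam)),
               sample(domIdx, k)) else integer(0)
    aaLen <- nchar(familyReference(fam))
    for (gi in carrierIdx)
      for (cp in seq_len(carriage$copies[r]))
        genes[[length(genes) + 1L]] <- addGene(genomeId[gi], fam, aaLen, cp)
    domAb <- sum(relAb[domIdx])
    truth[[fam]] <- list(
      genomeCarriage = if (length(domIdx)) k / length(domIdx) else 0,
      communityCarriage = if (domAb > 0) sum(relAb[carrierIdx]) / domAb else 0,
      carriers = data.frame(genomeId = genomeId[carrierIdx],
                            taxonId = unname(taxa[carrierIdx]),
                            relAbundance = relAb[carrierIdx],
                            stringsAsFactors = FALSE))
  }
  # background genes
  if (backgroundGenes > 0L) {
    aaLens <- withSeed(deriveSeed(seed, "background:lengths"), {
      pmax(60L, round(rlnorm(nGenomes * backgroundGenes,
                             lengthModel[["meanlog"]],
                             lengthModel[["sdlog"]])))
    })
    k <- 0L
    for (i in seq_len(nGenomes))
      for (b in seq_len(backgroundGenes)) {
        k <- k + 1L
        genes[[length(genes) + 1L]] <-
          addGene(genomeId[i], "background", aaLens[k], b)
      }
  }
  new("SyntheticCommunity", genomes = genomes,
      genes = do.call(rbind, genes), truth = truth,
      seed = as.integer(seed))
}

#' Accessors for SyntheticCommunity
#' @param x A \linkS4class{SyntheticCommunity}.
#' @return \code{communityGenomes} / \code{communityGenes}: the underlying
#'   tables; \code{communityTruth}: the recorded ground truth.
#' @export
communityGenomes <- function(x) x@genomes

#' @rdname communityGenomes
#' @export
communityGenes <- function(x) x@genes

#' @rdname communityGenomes
#' @export
communityTruth <- function(x) x@truth

#' Materialize protein sequences for a community's genes
#'
#' Marker genes are mutants of the recA / beta-actin references at
#' \code{markerDivergence}; planted family genes are mutants of the family
#' reference at \code{geneDivergence}, or of the carrier genus's database
#' variant at \code{refDivergence} when a reference database is supplied
#' (so taxonomic attribution has signal); background genes are random
#' proteins at background composition.
#'
#' @param community A \linkS4class{SyntheticCommunity}.
#' @param geneDivergence Divergence of planted genes from the family
#'   reference (default 0.3).
#' @param markerDivergence Divergence of marker genes (default 0.1).
#' @param referenceDB Optional result of
#'   \code{\link{makeSyntheticReferenceDB}}.
#' @param refDivergence Divergence from the genus variant when
#'   \code{referenceDB} is given (default 0.15).
#' @return Named character vector geneId -> protein.
#' @export
communityProteins <- function(community, geneDivergence = 0.3,
                              markerDivergence = 0.1, referenceDB = NULL,
                              refDivergence = 0.15) {
  g <- community@genes
  genomes <- community@genomes
  genusOf <- setNames(genomes$taxonId, genomes$genomeId)
  seed <- community@seed
  out <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    fam <- g$family[i]
    aaLen <- g$ntLength[i] / 3
    gseed <- deriveSeed(seed, paste0("prot:", g$geneId[i]))
    if (fam == "background") {
      out[i] <- randomProtein(aaLen, gseed)
    } else if (fam %in% c("RecA", "BetaActin")) {
      out[i] <- mutateFamilySequence(familyReference(fam),
                                     markerDivergence, gseed)
    } else {
      base <- NULL
      if (!is.null(referenceDB)) {
        refId <- paste0(fam, "@", genusOf[[g$genomeId[i]]])
        base <- referenceDB$proteins[[refId]]
      }
      out[i] <- if (!is.null(base))
        mutateFamilySequence(base, refDivergence, gseed)
      else
        mutateFamilySequence(familyReference(fam),
                             geneDivergence, gseed)
    }
  }
  setNames(out, g$geneId)
}

#' Simulate per-sample read counts for a community
#'
#' counts(gene, sample) ~ Poisson(meanDepth x relAbundance(genome) x
#' ntLength / referenceLength), independently per sample with per-sample
#' seeds derived from \code{seed}.  With \code{referenceLength} equal to
#' the mean gene length (the default), \code{meanDepth = d * nGenomes}
#' yields on average about d reads per gene.
#'
#' @param community A \linkS4class{SyntheticCommunity}.
#' @param meanDepth Expected reads for a unit-abundance, reference-length
#'   gene.
#' @param nSamples Number of samples (default 1).
#' @param referenceLength Length scale in nt (default: mean gene length).
#' @param seed Base seed (default: the community's).
#' @return Integer matrix genes x samples (dimnames gene / sample ids).
#' @export
simulateCounts <- function(community, meanDepth, nSamples = 1L,
                           referenceLength = NULL,
                           seed = community@seed) {
  g <- community@genes
  if (is.null(referenceLength)) referenceLength <- mean(g$ntLength)
  relAb <- setNames(community@genomes$relAbundance,
                    community@genomes$genomeId)
  lambda <- meanDepth * relAb[g$genomeId] * g$ntLength / referenceLength
  counts <- matrix(0L, nrow(g), nSamples,
                   dimnames = list(g$geneId,
                                   sprintf("S%02d", seq_len(nSamples))))
  for (s in seq_len(nSamples)) {
    counts[, s] <- withSeed(deriveSeed(seed, paste0("counts:", s)),
                            rpois(nrow(g), lambda))
  }
  counts
}

#' Simulated gene catalog in the formats the catalog module consumes
#'
#' @param community A \linkS4class{SyntheticCommunity}.
#' @param meanDepth,nSamples,referenceLength,seed Passed to
#'   \code{\link{simulateCounts}}.
#' @param withSequences Materialize protein sequences (default TRUE).
#' @param ... Passed to \code{\link{communityProteins}}.
#' @return List with \code{genes} (data.frame \code{geneId, contigId,
#'   ntLength[, protein]}) and \code{counts}.
#' @export
simulateCatalog <- function(community, meanDepth, nSamples = 1L,
                            referenceLength = NULL,
                            seed = community@seed,
                            withSequences = TRUE, ...) {
  g <- community@genes
  genes <- data.frame(geneId = g$geneId, contigId = g$genomeId,
                      ntLength = g$ntLength, family = g$family,
                      stringsAsFactors = FALSE)
  if (withSequences)
    genes$protein <- unname(communityProteins(community, ...))
  counts <- simulateCounts(community, meanDepth, nSamples,
                           referenceLength, seed)
  list(genes = genes, counts = counts)
}

#' Write a simulated catalog to disk
#'
#' Emits \code{genes.faa}, \code{genes.tsv} and \code{counts.tsv} in the
#' exact formats \code{\link{readGeneCatalog}} reads.
#'
#' @param catalog Result of \code{\link{simulateCatalog}} (with
#'   sequences).
#' @param dir Output directory (created if needed).
#' @export
writeSimulatedCatalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(setNames(catalog$genes$protein,
                                         catalog$genes$geneId))
  Biostrings::writeXStringSet(aa, file.path(dir, "genes.faa"))
  write.table(catalog$genes[, c("geneId", "contigId", "ntLength")],
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cts <- data.frame(geneId = rownames(catalog$counts), catalog$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cts, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Ground-truth hit table for a synthetic community
#'
#' Search-hit data.frame built from the simulator's own gene labels (every
#' planted family gene and marker, verified, E-value 0).  This bypasses
#' profile search and verification, isolating the abundance-normalization
#' stages so estimator error can be measured against the recorded truth
#' without detection noise.
#'
#' @param community A \linkS4class{SyntheticCommunity}.
#' @return data.frame \code{geneId, family, bitScore, eValue, verified}.
#' @export
truthHits <- function(community) {
  g <- community@genes
  keep <- g$family != "background"
  data.frame(geneId = g$geneId[keep], family = g$family[keep],
             bitScore = 10000, eValue = 0, verified = TRUE,
             stringsAsFactors = FALSE)
}

#' Synthetic reference database with per-genus family variants
#'
#' For each family and each genus of the family's domain, one mutant of
#' the family reference (divergence \code{divergence}) mapped to that
#' genus, giving the LCA assignment stage a database with genuine
#' genus-level signal.  All sequences are synthetic.
#'
#' @param taxonomy A \linkS4class{TaxonomyTree}.
#' @param families Families to include.
#' @param genera Optional named list restricting the genera per family.
#' @param divergence Variant divergence from the family reference
#'   (default 0.12).
#' @param seed Base seed.
#' @return List with \code{proteins} (named character), \code{mapping}
#'   (data.frame \code{referenceId, taxonId}) and \code{taxonomy}.
#' @export
makeSyntheticReferenceDB <- function(taxonomy, families,
                                     genera = NULL, divergence = 0.12,
                                     seed = 20200218L) {
  fd <- familyDomains()
  prot <- character(0)
  map <- list()
  for (fam in families) {
    dom <- fd$domain[match(fam, fd$family)]
    if (is.na(dom)) dom <- "Bacteria"
    gs <- if (!is.null(genera) && !is.null(genera[[fam]])) genera[[fam]]
          else genusNodes(taxonomy, dom)
    ref <- familyReference(fam, seed = seed)
    for (g in gs) {
      id <- paste0(fam, "@", g)
      prot[id] <- mutateFamilySequence(ref, divergence,
                                       deriveSeed(seed, paste0("db:", id)))
      map[[length(map) + 1L]] <- data.frame(referenceId = id, taxonId = g,
                                            stringsAsFactors = FALSE)
    }
  }
  list(proteins = prot, mapping = do.call(rbind, map), taxonomy = taxonomy)
}
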