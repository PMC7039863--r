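#' @include utils.R
#' @importClassesFrom Biostrings AAStringSet
NULL

.RANKS <- c("root", "domain", "phylum", "class", "order", "family",
            "genus", "species")

#' TrainingSet: ratified sequences for one gene family
#'
#' Holds the aligned, functionally verified (``ratified'') positive protein
#' sequences used to build a family profile, plus negative sequences from
#' families of different function used to place the score cutoff and to
#' verify candidates.
#'
#' @slot family Family identifier (e.g. "DsyB", "DmdA", "RecA").
#' @slot positives \linkS4class{AAStringSet} of aligned positives; all the
#'   same width, gaps allowed.
#' @slot negatives \linkS4class{AAStringSet} of unaligned negatives; may be
#'   empty.
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(family = "character",
                 positives = "AAStringSet",
                 negatives = "AAStringSet"))

setValidity("TrainingSet", function(object) {
  msgs <- character(0)
  if (length(object@family) != 1L || !nzchar(object@family))
    msgs <- c(msgs, "family must be a single non-empty string")
  if (length(object@positives) < 1L)
    msgs <- c(msgs, "at least one positive training sequence is required")
  w <- Biostrings::width(object@positives)
  if (length(w) > 0L && length(unique(w)) != 1L)
    msgs <- c(msgs, "positives must all have the same aligned length")
  ok <- c(AA20, AA_AMBIG, AA_GAPS)
  letters <- unique(unlist(strsplit(
    as.character(c(object@positives, object@negatives)), "", fixed = TRUE)))
  bad <- setdiff(letters, ok)
  if (length(bad) > 0L)
    msgs <- c(msgs, paste("invalid residue symbols:", paste(bad, collapse = " ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a TrainingSet
#'
#' @param family Family name.
#' @param positives Aligned positive sequences (character vector or
#'   \linkS4class{AAStringSet}); equal widths, gaps allowed.
#' @param negatives Negative (different-function) sequences; may be empty.
#' @return A \linkS4class{TrainingSet}.
#' @export
#' @examples
#' ts <- trainingSet("Toy", c(a = "ACDEF", b = "ACDEY"), c(n1 = "WWWWW"))
#' ts
trainingSet <- function(family, positives, negatives = character(0)) {
  if (length(positives) == 0L)
    stop("missing training data: no positive sequences for family ", family)
  pos <- Biostrings::AAStringSet(positives)
  if (length(unique(Biostrings::width(pos))) > 1L)
    stop("ragged alignment: positive sequences for family ", family,
         " differ in aligned length")
  new("TrainingSet", family = family, positives = pos,
      negatives = Biostrings::AAStringSet(negatives))
}

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet for family", object@family, "\n",
      length(object@positives), "positives (aligned width",
      if (length(object@positives)) Biostrings::width(object@positives)[1] else 0,
      "),", length(object@negatives), "negatives\n")
})

#' ProfileModel: per-family profile scoring model
#'
#' A Plan7-style profile with per-column match emissions, match/insert/delete
#' transition probabilities, a background null model, a bit-score cutoff
#' derived from the family's training data, and a Gumbel (extreme-value)
#' calibration converting bit scores to E-values.
#'
#' @slot family Family identifier.
#' @slot matchEmissions L x 20 matrix; each row a distribution over the 20
#'   amino acids (columns in alphabetical one-letter order).
#' @slot transitions List of 7 probability vectors of length L-1:
#'   \code{mm, mi, md} (from match j), \code{im, ii} (from insert j),
#'   \code{dm, dd} (from delete j); each bundle sums to 1 per position.
#' @slot background Length-20 null distribution.
#' @slot pseudocountWeight Total pseudocount mass used when the profile was
#'   built (needed to rebuild leave-one-out profiles consistently).
#' @slot scoreCutoff Family bit-score cutoff (NA until derived).
#' @slot evdLambda,evdMu Gumbel slope/location of the decoy score
#'   distribution (NA until calibrated); \code{evdLambda > 0}.
#' @slot decoyCount Number of decoys used in calibration.
#' @exportClass ProfileModel
setClass("ProfileModel",
  representation(family = "character",
                 matchEmissions = "matrix",
                 transitions = "list",
                 background = "numeric",
                 pseudocountWeight = "numeric",
                 scoreCutoff = "numeric",
                 evdLambda = "numeric",
                 evdMu = "numeric",
                 decoyCount = "integer"))

setValidity("ProfileModel", function(object) {
  msgs <- character(0)
  tol <- 1e-9
  E <- object@matchEmissions
  if (nrow(E) < 1L || ncol(E) != 20L)
    msgs <- c(msgs, "matchEmissions must be an L x 20 matrix with L >= 1")
  else if (any(abs(rowSums(E) - 1) > tol))
    msgs <- c(msgs, "each match emission row must sum to 1")
  if (abs(sum(object@background) - 1) > tol)
    msgs <- c(msgs, "background must sum to 1")
  tr <- object@transitions
  need <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  if (!all(need %in% names(tr))) {
    msgs <- c(msgs, "transitions must contain mm, mi, md, im, ii, dm, dd")
  } else if (nrow(E) > 1L) {
    Lm1 <- nrow(E) - 1L
    if (any(vapply(tr[need], length, 1L) != Lm1)) {
      msgs <- c(msgs, "each transition vector must have length L-1")
    } else {
      if (any(abs(tr$mm + tr$mi + tr$md - 1) > tol))
        msgs <- c(msgs, "match transition bundles must sum to 1")
      if (any(abs(tr$im + tr$ii - 1) > tol))
        msgs <- c(msgs, "insert transition bundles must sum to 1")
      if (any(abs(tr$dm + tr$dd - 1) > tol))
        msgs <- c(msgs, "delete transition bundles must sum to 1")
    }
  }
  if (!is.na(object@evdLambda) && object@evdLambda <= 0)
    msgs <- c(msgs, "evdLambda must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ProfileModel", function(object) {
  cat("ProfileModel", object@family, "-", nrow(object@matchEmissions),
      "match columns\n")
  cat("  score cutoff:", if (is.na(object@scoreCutoff)) "not derived"
      else sprintf("%.2f bits", object@scoreCutoff), "\n")
  cat("  E-value calibration:", if (is.na(object@evdLambda)) "not calibrated"
      else sprintf("Gumbel lambda = %.4f, mu = %.2f (%d decoys)",
                   object@evdLambda, object@evdMu, object@decoyCount), "\n")
})

#' TaxonomyTree: reference taxonomy for LCA assignment
#'
#' A rooted taxonomy in NCBI-dump-like form: one row per node with its
#' parent, rank and name.  Parent pointers must be acyclic and every node
#' must reach the root.
#'
#' @slot nodes data.frame with columns \code{nodeId, parentId, rank, name}.
#' @slot root Node id of the root (its own parent).
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
  representation(nodes = "data.frame", root = "character"))

setValidity("TaxonomyTree", function(object) {
  nd <- object@nodes
  msgs <- character(0)
  need <- c("nodeId", "parentId", "rank", "name")
  if (!all(need %in% colnames(nd)))
    return("nodes must have columns nodeId, parentId, rank, name")
  if (anyDuplicated(nd$nodeId)) msgs <- c(msgs, "duplicate node ids")
  if (!(object@root %in% nd$nodeId)) msgs <- c(msgs, "root not among nodes")
  if (!all(nd$rank %in% .RANKS))
    msgs <- c(msgs, paste("ranks must be among:", paste(.RANKS, collapse = " ")))
  parent <- setNames(nd$parentId, nd$nodeId)
  if (!all(nd$parentId %in% nd$nodeId))
    msgs <- c(msgs, "every parentId must be a node")
  else {
    for (id in nd$nodeId) {
      seen <- character(0)
      cur <- id
      repeat {
        if (cur == object@root) break
        if (cur %in% seen) { msgs <- c(msgs, "cycle in parent pointers"); break }
        seen <- c(seen, cur)
        cur <- parent[[cur]]
        if (length(seen) > nrow(nd)) { msgs <- c(msgs, "node cannot reach root"); break }
      }
      if (length(msgs)) break
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TaxonomyTree", function(object) {
  cat("TaxonomyTree with", nrow(object@nodes), "nodes, root =",
      object@root, "\n")
  print(table(factor(object@nodes$rank, levels = .RANKS)))
})

#' CalibrationCurve: headspace-DMS calibration line
#'
#' Ordinary least-squares fit of instrument response against known DMS
#' amounts, with the assay detection limit used for censoring.
#'
#' @slot standards data.frame with columns \code{amount} (nmol) and
#'   \code{response} (arbitrary units).
#' @slot slope,intercept Fitted line \code{response = slope * amount +
#'   intercept}.
#' @slot rSquared Coefficient of determination.
#' @slot detectionLimit Headspace DMS detection limit in nmol (default
#'   0.015).
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(standards = "data.frame", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric",
                 detectionLimit = "numeric"))

setValidity("CalibrationCurve", function(object) {
  msgs <- character(0)
  if (nrow(object@standards) < 3L)
    msgs <- c(msgs, "at least 3 calibration standards are required")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msgs <- c(msgs, "rSquared must lie in [0, 1]")
  if (object@detectionLimit <= 0)
    msgs <- c(msgs, "detectionLimit must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: response = %.4g * amount + %.4g (r^2 = %.4f)\n",
    object@slope, object@intercept, object@rSquared))
  cat(sprintf("  %d standards, detection limit %.3f nmol\n",
              nrow(object@standards), object@detectionLimit))
})

#' SyntheticCommunity: simulated community with recorded ground truth
#'
#' @slot genomes data.frame: \code{genomeId, domain, taxonId,
#'   relAbundance}; relative abundances sum to 1.
#' @slot genes data.frame: \code{geneId, genomeId, family, ntLength} where
#'   \code{family} is a gene-family label, "RecA"/"BetaActin" for the
#'   single-copy markers, or "background".
#' @slot truth Named list per planted family: \code{genomeCarriage}
#'   (fraction of genomes of the family's domain carrying it),
#'   \code{communityCarriage} (abundance-weighted fraction of the domain's
#'   cells carrying it — the quantity marker normalization estimates), and
#'   \code{carriers} (data.frame of carrier genomes with their genus).
#' @slot seed Base seed the community was generated from.
#' @exportClass SyntheticCommunity
setClass("SyntheticCommunity",
  representation(genomes = "data.frame", genes = "data.frame",
                 truth = "list", seed = "integer"))

setValidity("SyntheticCommunity", function(object) {
  msgs <- character(0)
  g <- object@genomes
  if (abs(sum(g$relAbundance) - 1) > 1e-9)
    msgs <- c(msgs, "relative abundances must sum to 1")
  genes <- object@genes
  bact <- g$genomeId[g$domain == "Bacteria"]
  euk <- g$genomeId[g$domain == "Eukaryota"]
  recA <- table(factor(genes$genomeId[genes$family == "RecA"], levels = bact))
  if (length(bact) && any(recA != 1L))
    msgs <- c(msgs, "every bacterial genome must carry exactly one recA")
  act <- table(factor(genes$genomeId[genes$family == "BetaActin"], levels = euk))
  if (length(euk) && any(act != 1L))
    msgs <- c(msgs, "every eukaryotic genome must carry exactly one beta-actin")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticCommunity", function(object) {
  cat("SyntheticCommunity:", nrow(object@genomes), "genomes (",
      sum(object@genomes$domain == "Bacteria"), "bacterial,",
      sum(object@genomes$domain == "Eukaryota"), "eukaryotic ),",
      nrow(object@genes), "genes\n")
  for (fam in names(object@truth)) {
    tr <- object@truth[[fam]]
    cat(sprintf("  %s: %.1f%% of genomes, %.1f%% of cells\n", fam,
                100 * tr$genomeCarriage, 100 * tr$communityCarriage))
  }
})

#' CensusTable: per-sample community fractions for each gene family
#'
#' The quantitative endpoint of the pipeline: for each sample and family,
#' the percentage of the bacterial (recA-normalized) or eukaryotic
#' (beta-actin-normalized) community carrying the family, with the
#' underlying summed abundances and optional group means.
#'
#' @slot fractions family x sample matrix of percentages (NA where the
#'   marker denominator was undefined).
#' @slot geneAbundance family x sample matrix of summed verified-hit
#'   abundances (reads per base).
#' @slot markerAbundance marker x sample matrix of denominators.
#' @slot groupMeans family x group matrix of arithmetic mean percentages
#'   (samples with undefined fractions excluded per cell).
#' @slot groups data.frame \code{sampleId, group} (possibly empty).
#' @exportClass CensusTable
setClass("CensusTable",
  representation(fractions = "matrix", geneAbundance = "matrix",
                 markerAbundance = "matrix", groupMeans = "matrix",
                 groups = "data.frame"))

setMethod("show", "CensusTable", function(object) {
  cat("CensusTable:", nrow(object@fractions), "families x",
      ncol(object@fractions), "samples (% of community carrying gene)\n")
  print(round(object@fractions, 2))
  if (ncol(object@groupMeans) > 0) {
    cat("Group means (%):\n")
    print(round(object@groupMeans, 2))
  }
})
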