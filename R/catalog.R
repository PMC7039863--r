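#' @include utils.R
NULL

#' Filter contigs by minimum length
#'
#' Retains contigs strictly longer than \code{minLength} (a 500 bp contig
#' is removed at the default).
#'
#' @param contigs data.frame with columns \code{contigId, length}.
#' @param minLength Minimum length in nucleotides (exclusive; default 500).
#' @return The retained rows of \code{contigs}.
#' @export
#' @examples
#' filterContigs(data.frame(contigId = c("a", "b"), length = c(500, 501)))
filterContigs <- function(contigs, minLength = 500) {
  stopifnot(all(c("contigId", "length") %in% colnames(contigs)))
  contigs[contigs$length > minLength, , drop = FALSE]
}

#' Greedy incremental clustering of catalog proteins
#'
#' Genes are processed in order of decreasing nucleotide length (ties
#' broken by gene id); each gene joins the first existing cluster whose
#' representative it matches at \code{>= identity} over \code{>= coverage}
#' of the shorter sequence, otherwise it founds a new cluster.  Because of
#' the processing order the founder is always the longest member, so the
#' founder is the cluster representative.  Identity is computed over the
#' aligned columns of a BLOSUM62 global alignment of the shorter sequence
#' onto the longer; coverage is the aligned fraction of the shorter
#' sequence.  A 5-mer prescreen skips alignments that cannot reach the
#' identity threshold.
#'
#' @param genes data.frame with columns \code{geneId, ntLength, protein}.
#' @param identity Minimum identity in (0, 1]; default 0.95.
#' @param coverage Minimum coverage of the shorter sequence in (0, 1];
#'   default 0.90.
#' @return data.frame \code{geneId, representativeId}, one row per input
#'   gene.
#' @export
clusterGenes <- function(genes, identity = 0.95, coverage = 0.90) {
  if (identity <= 0 || identity > 1 || coverage <= 0 || coverage > 1)
    stop("identity and coverage must lie in (0, 1]")
  if (nrow(genes) == 0L)
    return(data.frame(geneId = character(0), representativeId = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(-genes$ntLength, genes$geneId)
  g <- genes[ord, , drop = FALSE]
  reps <- integer(0)            # row indices (into g) of representatives
  repKmers <- list()
  assign <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    km <- .kmers(g$protein[i])
    placed <- FALSE
    for (r in seq_along(reps)) {
      j <- reps[r]
      shorter <- min(nchar(g$protein[i]), nchar(g$protein[j]))
      if (!.kmerPrescreen(km, repKmers[[r]], shorter)) next
      idcov <- .pairIdentity(g$protein[i], g$protein[j])
      if (idcov[["identity"]] >= identity && idcov[["coverage"]] >= coverage) {
        assign[i] <- g$geneId[j]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      repKmers[[length(reps)]] <- km
      assign[i] <- g$geneId[i]
    }
  }
  out <- data.frame(geneId = g$geneId, representativeId = assign,
                    stringsAsFactors = FALSE)
  out[match(genes$geneId, out$geneId), , drop = FALSE]
}

#' Length-normalized abundance table
#'
#' abundance(gene, sample) = mapped reads / gene nucleotide length (reads
#' per base).  Gene-sample pairs with fewer than \code{minReads} mapped
#' reads are discarded (no entry).
#'
#' @param genes data.frame with columns \code{geneId, ntLength}.
#' @param counts Integer matrix genes x samples (rownames = gene ids,
#'   colnames = sample ids).
#' @param minReads Minimum mapped reads per gene-sample pair (default 2).
#' @return Long data.frame \code{geneId, sampleId, abundance}.
#' @export
#' @examples
#' cts <- matrix(c(10L, 1L), 1, 2, dimnames = list("g1", c("A", "B")))
#' computeAbundance(data.frame(geneId = "g1", ntLength = 1000), cts)
computeAbundance <- function(genes, counts, minReads = 2) {
  stopifnot(all(rownames(counts) %in% genes$geneId))
  ntl <- setNames(genes$ntLength, genes$geneId)[rownames(counts)]
  if (any(ntl <= 0)) stop("gene nucleotide lengths must be positive")
  keep <- which(counts >= minReads, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    return(data.frame(geneId = character(0), sampleId = character(0),
                      abundance = numeric(0), stringsAsFactors = FALSE))
  out <- data.frame(
    geneId = rownames(counts)[keep[, 1]],
    sampleId = colnames(counts)[keep[, 2]],
    abundance = counts[keep] / ntl[keep[, 1]],
    stringsAsFactors = FALSE)
  out <- out[order(out$sampleId, out$geneId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene catalog from FASTA + metadata + counts files
#'
#' @param fastaPath Protein FASTA of catalog genes.
#' @param metaPath TSV with columns \code{geneId, contigId, ntLength}.
#' @param countsPath TSV count matrix, first column gene ids, remaining
#'   columns samples.
#' @return List with \code{genes} (data.frame incl. \code{protein}) and
#'   \code{counts} (integer matrix).
#' @export
readGeneCatalog <- function(fastaPath, metaPath, countsPath = NULL) {
  aa <- Biostrings::readAAStringSet(fastaPath)
  meta <- read.delim(metaPath, stringsAsFactors = FALSE)
  stopifnot(all(c("geneId", "contigId", "ntLength") %in% colnames(meta)))
  ids <- sub("\\s.*$", "", names(aa))
  if (!all(meta$geneId %in% ids))
    stop("metadata gene ids missing from FASTA")
  genes <- meta
  genes$protein <- as.character(aa)[match(meta$geneId, ids)]
  counts <- NULL
  if (!is.null(countsPath)) {
    ctab <- read.delim(countsPath, stringsAsFactors = FALSE, check.names = FALSE)
    counts <- as.matrix(ctab[, -1, drop = FALSE])
    rownames(counts) <- ctab[[1]]
    storage.mode(counts) <- "integer"
  }
  list(genes = genes, counts = counts)
}

#' Write an abundance table as long-format TSV
#'
#' @param table Long data.frame from \code{\link{computeAbundance}}.
#' @param path Output TSV path.
#' @export
writeAbundanceTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
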