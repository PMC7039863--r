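#' @include AllClasses.R
NULL

#' Construct / read a taxonomy tree
#'
#' @param nodes data.frame with columns \code{nodeId, parentId, rank,
#'   name}; the root is the node that is its own parent.
#' @return A \linkS4class{TaxonomyTree}.
#' @export
taxonomyTree <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$nodeId <- as.character(nodes$nodeId)
  nodes$parentId <- as.character(nodes$parentId)
  root <- nodes$nodeId[nodes$nodeId == nodes$parentId]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root (node that is its own parent)")
  new("TaxonomyTree", nodes = nodes, root = root)
}

#' @rdname taxonomyTree
#' @param path TSV file with the four node columns.
#' @export
readTaxonomy <- function(path) {
  taxonomyTree(read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character"))
}

#' @rdname taxonomyTree
#' @param tree A \linkS4class{TaxonomyTree}.
#' @export
writeTaxonomy <- function(tree, path) {
  write.table(tree@nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Accessors for TaxonomyTree
#' @param x A \linkS4class{TaxonomyTree}.
#' @return \code{taxNodes}: the node table; \code{taxRoot}: the root id.
#' @export
taxNodes <- function(x) x@nodes

#' @rdname taxNodes
#' @export
taxRoot <- function(x) x@root

# root-to-node path (inclusive)
.lineage <- function(tree, nodeId) {
  parent <- setNames(tree@nodes$parentId, tree@nodes$nodeId)
  if (!nodeId %in% names(parent))
    stop("taxonomy integrity error: unknown taxon id ", nodeId)
  path <- nodeId
  while (nodeId != tree@root) {
    nodeId <- parent[[nodeId]]
    path <- c(nodeId, path)
  }
  path
}

# ancestor of nodeId at the given rank, or NA if the lineage skips it
.ancestorAtRank <- function(tree, nodeId, rank) {
  lin <- .lineage(tree, nodeId)
  ranks <- tree@nodes$rank[match(lin, tree@nodes$nodeId)]
  hit <- lin[ranks == rank]
  if (length(hit)) hit[length(hit)] else NA_character_
}

#' Lowest-common-ancestor assignment of a gene
#'
#' Hits below \code{minScore} bits are dropped; of the rest, those scoring
#' within \code{topFraction} of the best bit score are retained and the
#' gene is assigned to the lowest common ancestor of their taxa.  With
#' \code{bestHitOnly = TRUE} only the top-scoring hits (ties included) are
#' retained before the LCA.
#'
#' @param hitset data.frame with columns \code{taxonId, bitScore} (one row
#'   per reference hit of one gene).
#' @param tree A \linkS4class{TaxonomyTree}.
#' @param topFraction Retain hits with \code{bitScore >= (1 - topFraction)
#'   * best}; default 0.10.
#' @param minScore Minimum bit score (default 50).
#' @param bestHitOnly Use only the best hit(s) instead of the top-score
#'   band.
#' @return Node id, or \code{"unassigned"} when no hit passes the filter.
#' @export
assignLca <- function(hitset, tree, topFraction = 0.10, minScore = 50,
                      bestHitOnly = FALSE) {
  if (is.null(hitset) || nrow(hitset) == 0L) return("unassigned")
  keep <- hitset[hitset$bitScore >= minScore, , drop = FALSE]
  if (nrow(keep) == 0L) return("unassigned")
  best <- max(keep$bitScore)
  keep <- if (bestHitOnly) keep[keep$bitScore == best, , drop = FALSE]
          else keep[keep$bitScore >= (1 - topFraction) * best, , drop = FALSE]
  taxa <- unique(as.character(keep$taxonId))
  bad <- setdiff(taxa, tree@nodes$nodeId)
  if (length(bad))
    stop("taxonomy integrity error: unknown taxon id(s) ",
         paste(bad, collapse = ", "))
  cur <- taxa[1]
  for (t in taxa[-1]) cur <- .pairLca(tree, cur, t)
  cur
}

# pairwise LCA by lifting the deeper node to equal depth, then both
.pairLca <- function(tree, a, b) {
  parent <- setNames(tree@nodes$parentId, tree@nodes$nodeId)
  depth <- function(x) length(.lineage(tree, x))
  da <- depth(a); db <- depth(b)
  while (da > db) { a <- parent[[a]]; da <- da - 1L }
  while (db > da) { b <- parent[[b]]; db <- db - 1L }
  while (a != b) { a <- parent[[a]]; b <- parent[[b]] }
  a
}

#' Cumulative taxon abundance in a sample
#'
#' The abundance of a taxon is the sum of abundances of genes assigned to
#' it or to any of its descendants (cumulative rollup); unassigned genes
#' are totalled separately.
#'
#' @param assignments Named character vector gene id -> node id (may
#'   include \code{"unassigned"}).
#' @param table Long abundance data.frame.
#' @param sample Sample id.
#' @param tree A \linkS4class{TaxonomyTree}.
#' @return List with \code{abundance} (named numeric per node) and
#'   \code{unassigned} (total).
#' @export
taxonAbundance <- function(assignments, table, sample, tree) {
  tab <- table[table$sampleId == sample, , drop = FALSE]
  acc <- new.env(parent = emptyenv())
  unassigned <- 0
  for (i in seq_len(nrow(tab))) {
    g <- tab$geneId[i]
    node <- assignments[[g]]
    if (is.null(node) || is.na(node)) next
    if (node == "unassigned") {
      unassigned <- unassigned + tab$abundance[i]
      next
    }
    for (anc in .lineage(tree, node)) {
      prev <- if (exists(anc, envir = acc)) get(anc, envir = acc) else 0
      assign(anc, prev + tab$abundance[i], envir = acc)
    }
  }
  nodes <- ls(acc)
  list(abundance = setNames(vapply(nodes, get, numeric(1), envir = acc),
                            nodes),
       unassigned = unassigned)
}

#' Genera carrying a gene family, ranked by abundance
#'
#' For each verified hit of the family, its taxonomic assignment is mapped
#' to the genus rank (assignments below genus are lifted to their genus;
#' assignments above genus are kept under their own rank and labelled with
#' it), and genera are ranked by the summed abundance of the family's genes.
#'
#' @param family Family name.
#' @param verified Verified hits data.frame.
#' @param assignments Named character vector gene id -> node id.
#' @param table Long abundance data.frame.
#' @param sample Sample id.
#' @param tree A \linkS4class{TaxonomyTree}.
#' @return data.frame \code{taxonId, name, rank, abundance} sorted by
#'   decreasing abundance.
#' @export
taxaWithGene <- function(family, verified, assignments, table, sample, tree) {
  vh <- verified[verified$family == family & !is.na(verified$verified) &
                   verified$verified, , drop = FALSE]
  tab <- table[table$sampleId == sample & table$geneId %in% vh$geneId, ,
               drop = FALSE]
  if (nrow(tab) == 0L)
    return(data.frame(taxonId = character(0), name = character(0),
                      rank = character(0), abundance = numeric(0),
                      stringsAsFactors = FALSE))
  nd <- tree@nodes
  rankOf <- setNames(nd$rank, nd$nodeId)
  lab <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    node <- assignments[[tab$geneId[i]]]
    if (is.null(node) || is.na(node) || node == "unassigned") {
      lab[i] <- "unassigned"
      next
    }
    r <- rankOf[[node]]
    if (r == "species") {
      g <- .ancestorAtRank(tree, node, "genus")
      lab[i] <- if (is.na(g)) node else g
    } else {
      lab[i] <- node          # genus kept; above-genus kept under own rank
    }
  }
  agg <- tapply(tab$abundance, lab, sum)
  out <- data.frame(
    taxonId = names(agg),
    name = ifelse(names(agg) == "unassigned", "unassigned",
                  nd$name[match(names(agg), nd$nodeId)]),
    rank = ifelse(names(agg) == "unassigned", "unassigned",
                  rankOf[names(agg)]),
    abundance = as.numeric(agg), stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$taxonId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align catalog genes to a reference database for taxonomic assignment
#'
#' Local BLOSUM62 alignment of each gene against every reference protein
#' (the same aligner the catalog clustering uses); bit scores are raw
#' alignment scores halved (BLOSUM62 is in half-bit units).  A 5-mer
#' prescreen skips hopeless pairs.
#'
#' @param genes data.frame with \code{geneId, protein}.
#' @param reference Named character vector (or \code{AAStringSet}) of
#'   reference proteins.
#' @param mapping data.frame \code{referenceId, taxonId}.
#' @param minScore Report hits at or above this bit score (default 50).
#' @param prescreen Use the 5-mer prescreen (default TRUE).
#' @return Named list per gene of hit data.frames (\code{referenceId,
#'   taxonId, bitScore}).
#' @export
searchReference <- function(genes, reference, mapping, minScore = 50,
                            prescreen = TRUE) {
  refs <- setNames(as.character(reference), names(reference))
  stopifnot(all(names(refs) %in% mapping$referenceId) ||
              all(mapping$referenceId %in% names(refs)))
  taxOf <- setNames(as.character(mapping$taxonId), mapping$referenceId)
  refKmers <- lapply(refs, .kmers)
  out <- vector("list", nrow(genes))
  names(out) <- genes$geneId
  for (i in seq_len(nrow(genes))) {
    q <- genes$protein[i]
    km <- .kmers(q)
    rows <- list()
    for (r in names(refs)) {
      if (prescreen) {
        # permissive screen: any shared 5-mer at all
        if (sum(km %in% refKmers[[r]]) < 1L) next
      }
      bits <- .alnScore(q, refs[[r]]) / 2
      if (bits >= minScore)
        rows[[length(rows) + 1L]] <- data.frame(
          referenceId = r, taxonId = taxOf[[r]], bitScore = bits,
          stringsAsFactors = FALSE)
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows)
      else data.frame(referenceId = character(0), taxonId = character(0),
                      bitScore = numeric(0), stringsAsFactors = FALSE)
  }
  out
}
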