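#' @include AllClasses.R profiles.R
NULL

#' Family-to-domain configuration
#'
#' Static mapping of each gene family to the domain whose single-copy
#' marker normalizes it: eukaryotic DMSP genes (DSYB, Alma1 and the
#' TpMMT-class methyltransferases) are normalized by beta-actin, every
#' bacterial family by recA.
#'
#' @return data.frame with columns \code{family, domain, marker}.
#' @export
#' @examples
#' familyDomains()
familyDomains <- function() {
  fams <- c("DddD", "DddK", "DddL", "DddP", "DddQ", "DddY", "DddW",
            "Alma1", "DsyB", "DSYB", "MmtN", "DmdA", "DmdB", "DmdC",
            "DmdD", "AcuH", "MddA", "DmoA", "DdhA", "Tmm", "MTO",
            "DMSOR", "TpMMT")
  euk <- c("DSYB", "Alma1", "TpMMT")
  domain <- ifelse(fams %in% euk, "Eukaryota", "Bacteria")
  data.frame(family = fams, domain = domain,
             marker = ifelse(domain == "Eukaryota", "BetaActin", "RecA"),
             stringsAsFactors = FALSE)
}

#' Single-copy marker specification
#'
#' recA (bacteria) and beta-actin (eukaryotes) are used as single-copy
#' community denominators, with E-value cutoffs of 1e-50 and 1e-60
#' respectively.
#'
#' @param marker "RecA" or "BetaActin".
#' @param eValueCutoff Override the default E-value cutoff.
#' @return List with \code{marker} and \code{eValueCutoff}.
#' @export
markerSpec <- function(marker = c("RecA", "BetaActin"), eValueCutoff = NULL) {
  marker <- match.arg(marker)
  if (is.null(eValueCutoff))
    eValueCutoff <- if (marker == "RecA") 1e-50 else 1e-60
  stopifnot(eValueCutoff > 0)
  list(marker = marker, eValueCutoff = eValueCutoff)
}

# marker spec for a family, via the static domain table
.markerFor <- function(family) {
  fd <- familyDomains()
  dom <- fd$marker[match(family, fd$family)]
  if (is.na(dom)) dom <- "RecA"
  markerSpec(dom)
}

#' Verify candidate hits against ratified references
#'
#' Each candidate is aligned (local, BLOSUM62) against all positives and
#' negatives of its family; it is verified iff its best-scoring reference
#' is a positive (ties count against, conservatively).  Genes hitting
#' several families keep only the family with the highest bit score.
#' Families without negatives fall back to cutoff-only acceptance with a
#' warning.
#'
#' @param hits data.frame from \code{\link{searchCatalog}}.
#' @param genes Catalog data.frame with \code{geneId, protein}.
#' @param training Named list of \linkS4class{TrainingSet}s keyed by
#'   family.
#' @return \code{hits} with \code{verified} filled in, one row per gene
#'   (its best family), unverified rows retained with
#'   \code{verified = FALSE}.
#' @export
verifyCandidates <- function(hits, genes, training) {
  if (nrow(hits) == 0L) return(hits)
  # best family per gene
  ord <- order(hits$geneId, -hits$bitScore, hits$family)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$geneId), , drop = FALSE]
  prot <- setNames(genes$protein, genes$geneId)
  degap <- function(x) gsub("[-.]", "", x)
  verified <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ts <- training[[hits$family[i]]]
    if (is.null(ts))
      stop("no training set for family ", hits$family[i])
    if (length(ts@negatives) == 0L) {
      warning("family ", hits$family[i], " has no negative references; ",
              "verification falls back to cutoff-only acceptance")
      verified[i] <- TRUE
      next
    }
    q <- prot[[hits$geneId[i]]]
    posBest <- max(vapply(degap(as.character(ts@positives)),
                          function(p) .alnScore(q, p), numeric(1)))
    negBest <- max(vapply(degap(as.character(ts@negatives)),
                          function(p) .alnScore(q, p), numeric(1)))
    verified[i] <- posBest > negBest
  }
  hits$verified <- verified
  rownames(hits) <- NULL
  hits
}

#' Marker-gene denominator for one sample
#'
#' Sum of abundances of marker hits passing the marker's E-value cutoff in
#' the sample; the fraction of the community carrying a functional gene is
#' its summed abundance divided by this denominator.
#'
#' @param table Long abundance data.frame (\code{geneId, sampleId,
#'   abundance}).
#' @param hits data.frame of search hits (marker families included).
#' @param marker A \code{\link{markerSpec}}.
#' @param sample Sample id.
#' @return Summed abundance (reads per base), or NA with a warning when no
#'   marker gene passes the cutoff in the sample.
#' @export
markerAbundance <- function(table, hits, marker, sample) {
  mh <- hits[hits$family == marker$marker &
               hits$eValue <= marker$eValueCutoff, , drop = FALSE]
  ab <- table[table$sampleId == sample &
                table$geneId %in% mh$geneId, , drop = FALSE]
  if (nrow(ab) == 0L) {
    warning("no ", marker$marker, " marker abundance in sample ", sample,
            "; community fractions are undefined for this sample")
    return(NA_real_)
  }
  tot <- sum(ab$abundance)
  if (tot <= 0) {
    warning("zero ", marker$marker, " abundance in sample ", sample)
    return(NA_real_)
  }
  tot
}

#' Community fraction carrying a gene family
#'
#' 100 x (summed abundance of verified family hits in the sample) /
#' (marker denominator).  Bacterial families are normalized by recA,
#' eukaryotic families by beta-actin.  Values above 100% (multi-copy
#' families) are reported unclamped with a warning.
#'
#' @param table Long abundance data.frame.
#' @param verified Verified hits data.frame (markers included).
#' @param family Family name.
#' @param marker A \code{\link{markerSpec}}; defaults to the family's
#'   domain marker from \code{\link{familyDomains}}.
#' @param sample Sample id.
#' @return Percentage of the domain community carrying \code{family}.
#' @export
communityFraction <- function(table, verified, family, sample,
                              marker = .markerFor(family)) {
  denom <- markerAbundance(table, verified, marker, sample)
  if (is.na(denom))
    stop("undefined ", marker$marker, " denominator for sample ", sample)
  vh <- verified[verified$family == family &
                   !is.na(verified$verified) & verified$verified, ,
                 drop = FALSE]
  ab <- table[table$sampleId == sample & table$geneId %in% vh$geneId, ,
              drop = FALSE]
  frac <- 100 * sum(ab$abundance) / denom
  if (frac > 100)
    warning("community fraction for ", family, " in ", sample,
            " exceeds 100% (multi-copy family?); reported unclamped")
  frac
}

#' Assemble the per-sample census table
#'
#' One column per sample with the percentage of the bacterial (recA) or
#' eukaryotic (beta-actin) community carrying each family, plus the
#' underlying summed abundances and optional arithmetic group means over
#' user-defined sample groups.  Samples whose marker denominator is
#' undefined get NA fractions and are excluded from group means with a
#' message.
#'
#' @param samples Character vector of sample ids.
#' @param table Long abundance data.frame.
#' @param verified Verified hits data.frame (marker hits included).
#' @param families Families to report (default: all with verified hits,
#'   in \code{\link{familyDomains}} order).
#' @param groups Optional data.frame \code{sampleId, group}.
#' @return A \linkS4class{CensusTable}.
#' @export
censusTable <- function(samples, table, verified, families = NULL,
                        groups = NULL) {
  if (!all(samples %in% table$sampleId))
    stop("unknown sample id(s): ",
         paste(setdiff(samples, table$sampleId), collapse = ", "))
  fd <- familyDomains()
  if (is.null(families)) {
    families <- intersect(fd$family, unique(verified$family))
    if (length(families) == 0L) stop("no families to report")
  }
  markers <- c("RecA", "BetaActin")
  frac <- matrix(NA_real_, length(families), length(samples),
                 dimnames = list(families, samples))
  gab <- frac
  mab <- matrix(NA_real_, 2, length(samples),
                dimnames = list(markers, samples))
  for (s in samples) {
    for (m in markers) {
      mab[m, s] <- tryCatch(
        suppressWarnings(markerAbundance(table, verified, markerSpec(m), s)),
        error = function(e) NA_real_)
    }
    for (f in families) {
      msp <- .markerFor(f)
      denom <- mab[msp$marker, s]
      vh <- verified[verified$family == f & !is.na(verified$verified) &
                       verified$verified, , drop = FALSE]
      ab <- table[table$sampleId == s & table$geneId %in% vh$geneId, ,
                  drop = FALSE]
      gab[f, s] <- sum(ab$abundance)
      if (!is.na(denom)) frac[f, s] <- 100 * gab[f, s] / denom
    }
  }
  gm <- matrix(numeric(0), length(families), 0, dimnames = list(families, NULL))
  if (!is.null(groups)) {
    stopifnot(all(c("sampleId", "group") %in% colnames(groups)))
    gl <- unique(groups$group)
    gm <- matrix(NA_real_, length(families), length(gl),
                 dimnames = list(families, gl))
    for (g in gl) {
      gs <- intersect(samples, groups$sampleId[groups$group == g])
      for (f in families) {
        v <- frac[f, gs]
        if (anyNA(v))
          message("group ", g, ": excluding sample(s) with undefined ",
                  f, " fraction from the mean")
        gm[f, g] <- mean(v, na.rm = TRUE)
      }
    }
  }
  new("CensusTable", fractions = frac, geneAbundance = gab,
      markerAbundance = mab, groupMeans = gm,
      groups = if (is.null(groups))
        data.frame(sampleId = character(0), group = character(0)) else groups)
}

#' Accessors for CensusTable
#'
#' @param x A \linkS4class{CensusTable}.
#' @return \code{censusFractions}: family x sample percentage matrix;
#'   \code{groupMeans}: family x group mean percentages;
#'   \code{markerDenominators}: marker x sample summed abundances.
#' @export
censusFractions <- function(x) x@fractions

#' @rdname censusFractions
#' @export
groupMeans <- function(x) x@groupMeans

#' @rdname censusFractions
#' @export
markerDenominators <- function(x) x@markerAbundance
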