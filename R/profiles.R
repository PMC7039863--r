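#' @include AllClasses.R
NULL

#' Build a profile model from a family training alignment
#'
#' Converts an aligned set of ratified positive sequences into a
#' Plan7-style profile: alignment columns with gap fraction below 0.5
#' become match columns (majority-occupancy rule), match emissions are
#' observed residue frequencies blended with background-proportional
#' pseudocounts, and match/insert/delete transitions are estimated from the
#' gap structure with Laplace pseudocounts.
#'
#' @param training A \linkS4class{TrainingSet}.
#' @param pseudocountWeight Total pseudocount mass added to each emission
#'   column (distributed proportionally to the background); default 1.
#' @return An uncalibrated \linkS4class{ProfileModel} (no score cutoff or
#'   E-value parameters yet; see \code{\link{deriveFamilyCutoff}} and
#'   \code{\link{calibrateEvalue}}).
#' @export
#' @examples
#' ts <- trainingSet("Toy", c("ACDE", "ACDE", "ACDD"))
#' buildProfile(ts)
buildProfile <- function(training, pseudocountWeight = 1) {
  stopifnot(is(training, "TrainingSet"), pseudocountWeight > 0)
  aln <- as.character(training@positives)
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  isGap <- matrix(mat %in% AA_GAPS, nrow = nrow(mat))
  gapFrac <- colMeans(isGap)
  matchCols <- which(gapFrac < 0.5)
  if (length(matchCols) == 0L)
    stop("no alignment column has majority occupancy; cannot build profile")
  bg <- aminoAcidBackground()
  L <- length(matchCols)

  # emissions: observed counts + background-proportional pseudocounts
  E <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    res <- mat[, matchCols[k]]
    res <- res[res %in% AA20]
    cnt <- table(factor(res, levels = AA20))
    e <- as.numeric(cnt) + pseudocountWeight * bg
    E[k, ] <- e / sum(e)
  }

  # transitions from per-sequence state paths over match/insert columns
  tr <- .estimateTransitions(mat, isGap, matchCols)

  new("ProfileModel", family = training@family, matchEmissions = E,
      transitions = tr, background = bg,
      pseudocountWeight = pseudocountWeight,
      scoreCutoff = NA_real_, evdLambda = NA_real_, evdMu = NA_real_,
      decoyCount = 0L)
}

# State-path transition counting.  Match column k of the profile is
# alignment column matchCols[k]; a residue there is M_k, a gap is D_k.
# Residues in non-match columns between matchCols[k] and matchCols[k+1]
# occupy insert state I_k.  Flanking residues before the first or after the
# last match column are unmodeled (local alignment absorbs them).
.estimateTransitions <- function(mat, isGap, matchCols) {
  L <- length(matchCols)
  nm <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  if (L == 1L) {
    tr <- setNames(rep(list(numeric(0)), 7), nm)
    return(tr)
  }
  cnt <- setNames(rep(list(rep(0, L - 1L)), 7), nm)
  for (s in seq_len(nrow(mat))) {
    for (k in seq_len(L - 1L)) {
      fromM <- !isGap[s, matchCols[k]]
      toM <- !isGap[s, matchCols[k + 1L]]
      between <- setdiff(seq(matchCols[k] + 1L, matchCols[k + 1L] - 1L),
                         matchCols)
      nIns <- if (matchCols[k + 1L] - matchCols[k] > 1L)
        sum(!isGap[s, between, drop = FALSE]) else 0L
      if (nIns > 0L) {
        # from-state -> I_k, (nIns-1) self loops, I_k -> to-state
        if (fromM) cnt$mi[k] <- cnt$mi[k] + 1
        # inserts reached from a delete are rare; count them as M->I too
        else cnt$mi[k] <- cnt$mi[k] + 1
        cnt$ii[k] <- cnt$ii[k] + (nIns - 1L)
        if (toM) cnt$im[k] <- cnt$im[k] + 1
        else { cnt$im[k] <- cnt$im[k] + 1 }  # I->D not modeled; treat as I->M
      } else {
        if (fromM && toM) cnt$mm[k] <- cnt$mm[k] + 1
        if (fromM && !toM) cnt$md[k] <- cnt$md[k] + 1
        if (!fromM && toM) cnt$dm[k] <- cnt$dm[k] + 1
        if (!fromM && !toM) cnt$dd[k] <- cnt$dd[k] + 1
      }
    }
  }
  norm <- function(parts) {
    tot <- Reduce(`+`, parts)
    lapply(parts, function(p) (p + 1) / (tot + length(parts)))
  }
  m <- norm(list(cnt$mm, cnt$mi, cnt$md))
  i <- norm(list(cnt$im, cnt$ii))
  d <- norm(list(cnt$dm, cnt$dd))
  list(mm = m[[1]], mi = m[[2]], md = m[[3]],
       im = i[[1]], ii = i[[2]], dm = d[[1]], dd = d[[2]])
}

# log2 forms used by the Viterbi kernel
.profileLogOdds <- function(profile) {
  log2(sweep(profile@matchEmissions, 2, profile@background, "/"))
}

.profileLogTrans <- function(profile) {
  lapply(profile@transitions, log2)
}

#' Score a protein sequence against a profile
#'
#' Maximum log2-odds local alignment score (best path over
#' match/insert/delete states, Smith-Waterman-style free entry into and
#' exit from any match state) of the query against the profile relative to
#' the background model.  The ambiguity residue X scores as background
#' (contribution 0) at match states.
#'
#' @param profile A \linkS4class{ProfileModel}.
#' @param query Protein sequence (single string or \code{AAString}).
#' @return Bit score (may be negative for unrelated sequences of length 1).
#' @export
#' @examples
#' p <- buildProfile(trainingSet("Toy", c("ACDE", "ACDE")))
#' scoreSequence(p, "ACDE") > scoreSequence(p, "AWDE")
scoreSequence <- function(profile, query) {
  stopifnot(is(profile, "ProfileModel"))
  q <- encodeProtein(as.character(query))
  .viterbiScore(.profileLogOdds(profile), .profileLogTrans(profile), q)
}

# batch scoring of many sequences (character vector)
.scoreMany <- function(profile, seqs) {
  qs <- lapply(as.character(seqs), encodeProtein)
  .viterbiScoreBatch(.profileLogOdds(profile), .profileLogTrans(profile), qs)
}

#' Calibrate a profile's E-value model on background decoys
#'
#' Scores i.i.d. decoy sequences sampled from the background residue
#' distribution and fits a Gumbel (extreme-value) distribution to the decoy
#' bit scores by the method of moments.  At search time
#' \code{E(S) = databaseSize * exp(-lambda * (S - mu))}.
#'
#' @param profile A \linkS4class{ProfileModel}.
#' @param decoyCount Number of decoys (>= 100).
#' @param decoyLength Decoy sequence length (default 150 residues).
#' @param seed RNG seed.
#' @return The profile with \code{evdLambda}, \code{evdMu} and
#'   \code{decoyCount} filled in.
#' @export
calibrateEvalue <- function(profile, decoyCount = 1000L, decoyLength = 150L,
                            seed = 20200218L) {
  stopifnot(is(profile, "ProfileModel"))
  if (decoyCount < 100L)
    stop("calibration underpowered: decoyCount must be >= 100")
  decoys <- randomProtein(rep(decoyLength, decoyCount),
                          deriveSeed(seed, paste0("decoys:", profile@family)))
  scores <- .scoreMany(profile, decoys)
  fit <- .fitGumbel(scores)
  profile@evdLambda <- fit[["lambda"]]
  profile@evdMu <- fit[["mu"]]
  profile@decoyCount <- as.integer(decoyCount)
  validObject(profile)
  profile
}

# Gumbel (max) method-of-moments fit: beta = sd * sqrt(6)/pi,
# mu = mean - Euler_gamma * beta, lambda = 1/beta.
.fitGumbel <- function(x) {
  eulerGamma <- 0.5772156649015329
  beta <- sd(x) * sqrt(6) / pi
  mu <- mean(x) - eulerGamma * beta
  c(lambda = 1 / beta, mu = mu)
}

#' E-value of a bit score under a calibrated profile
#'
#' @param profile Calibrated \linkS4class{ProfileModel}.
#' @param score Bit score(s).
#' @param databaseSize Number of sequences searched.
#' @return Expected number of false positives at or above \code{score}.
#' @export
evalueFromScore <- function(profile, score, databaseSize) {
  if (is.na(profile@evdLambda))
    stop("calibration missing: run calibrateEvalue() first")
  databaseSize * exp(-profile@evdLambda * (score - profile@evdMu))
}

#' Derive a family bit-score cutoff from its training data
#'
#' Leave-one-out positive scores are computed by scoring each positive
#' (ungapped) against a profile rebuilt from the remaining positives; the
#' cutoff is the midpoint between the minimum leave-one-out positive score
#' and the maximum negative score.  With no negatives the cutoff is the
#' minimum positive score minus \code{margin}.  If the maximum negative
#' score reaches the minimum positive score the training data are not
#' separable: a warning is emitted and the cutoff is set conservatively to
#' the minimum positive score.
#'
#' @param profile \linkS4class{ProfileModel} built from \code{training}.
#' @param training The matching \linkS4class{TrainingSet}.
#' @param margin Bits subtracted from the minimum positive score when no
#'   negatives are available (default 10).
#' @return The profile with \code{scoreCutoff} set.
#' @export
deriveFamilyCutoff <- function(profile, training, margin = 10) {
  stopifnot(is(profile, "ProfileModel"), is(training, "TrainingSet"))
  nPos <- length(training@positives)
  nNeg <- length(training@negatives)
  if (nPos < 2L && nNeg < 1L)
    stop("need >= 2 positives, or >= 1 positive and >= 1 negative")
  degap <- function(x) gsub("[-.]", "", x)
  posSeqs <- degap(as.character(training@positives))
  if (nPos >= 2L) {
    looScores <- vapply(seq_len(nPos), function(i) {
      sub <- trainingSet(training@family,
                         as.character(training@positives)[-i],
                         character(0))
      looProf <- buildProfile(sub, profile@pseudocountWeight)
      .scoreMany(looProf, posSeqs[i])
    }, numeric(1))
  } else {
    looScores <- .scoreMany(profile, posSeqs)
  }
  minPos <- min(looScores)
  if (nNeg >= 1L) {
    negScores <- .scoreMany(profile, as.character(training@negatives))
    maxNeg <- max(negScores)
    if (maxNeg >= minPos) {
      warning("training data for family ", profile@family,
              " are not separable; using conservative cutoff = min positive score")
      cutoff <- minPos
    } else {
      cutoff <- (minPos + maxNeg) / 2
    }
  } else {
    cutoff <- minPos - margin
  }
  profile@scoreCutoff <- cutoff
  profile
}

#' Search a gene catalog with calibrated family profiles
#'
#' Scores every catalog protein against every profile and reports hits at
#' or above each family's score cutoff, with Gumbel-calibrated E-values
#' (database size = number of catalog sequences).  A gene may hit several
#' families at this stage; \code{\link{verifyCandidates}} disambiguates.
#'
#' @param profiles List of calibrated \linkS4class{ProfileModel}s (cutoff
#'   and E-value parameters present).
#' @param genes Gene catalog data.frame with columns \code{geneId} and
#'   \code{protein}.
#' @return data.frame with columns \code{geneId, family, bitScore, eValue,
#'   verified} (verified is NA until verification).
#' @export
searchCatalog <- function(profiles, genes) {
  if (is(profiles, "ProfileModel")) profiles <- list(profiles)
  for (p in profiles) {
    if (is.na(p@scoreCutoff) || is.na(p@evdLambda))
      stop("calibration missing for family ", p@family,
           ": derive cutoff and E-value parameters first")
  }
  empty <- data.frame(geneId = character(0), family = character(0),
                      bitScore = numeric(0), eValue = numeric(0),
                      verified = logical(0), stringsAsFactors = FALSE)
  if (nrow(genes) == 0L) return(empty)
  out <- lapply(profiles, function(p) {
    sc <- .scoreMany(p, genes$protein)
    keep <- sc >= p@scoreCutoff
    if (!any(keep)) return(NULL)
    data.frame(geneId = genes$geneId[keep], family = p@family,
               bitScore = sc[keep],
               eValue = evalueFromScore(p, sc[keep], nrow(genes)),
               verified = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Read per-family training sets from a directory
#'
#' Expects \code{<dir>/<family>/positives.afa} (aligned FASTA) and
#' optionally \code{<dir>/<family>/negatives.fa}.
#'
#' @param dir Training directory.
#' @return Named list of \linkS4class{TrainingSet}s.
#' @export
readTrainingSets <- function(dir) {
  fams <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  out <- lapply(fams, function(f) {
    posFile <- file.path(dir, f, "positives.afa")
    if (!file.exists(posFile))
      stop("missing training data: ", posFile)
    pos <- Biostrings::readAAStringSet(posFile)
    negFile <- file.path(dir, f, "negatives.fa")
    neg <- if (file.exists(negFile))
      Biostrings::readAAStringSet(negFile) else Biostrings::AAStringSet()
    trainingSet(f, pos, neg)
  })
  setNames(out, fams)
}

#' Write / read a profile in the package's plain-text format
#'
#' Versioned per-column tables; numeric values carry 12 significant digits
#' so a write/read round trip is lossless at that precision.
#'
#' @param profile A \linkS4class{ProfileModel}.
#' @param path Output file.
#' @return \code{writeProfile} returns \code{path} invisibly;
#'   \code{readProfile} returns a \linkS4class{ProfileModel}.
#' @export
writeProfile <- function(profile, path) {
  fmt <- function(x) sprintf("%.12g", x)
  con <- file(path, "w")
  on.exit(close(con))
  L <- nrow(profile@matchEmissions)
  writeLines(c("sulfurCensus-profile v1",
               paste("family", profile@family),
               paste("length", L),
               paste("pseudocountWeight", fmt(profile@pseudocountWeight)),
               paste("scoreCutoff", fmt(profile@scoreCutoff)),
               paste("evdLambda", fmt(profile@evdLambda)),
               paste("evdMu", fmt(profile@evdMu)),
               paste("decoyCount", profile@decoyCount),
               paste(c("background", fmt(profile@background)), collapse = "\t")),
             con)
  writeLines("emissions", con)
  for (k in seq_len(L))
    writeLines(paste(fmt(profile@matchEmissions[k, ]), collapse = "\t"), con)
  writeLines("transitions mm mi md im ii dm dd", con)
  tr <- profile@transitions
  if (L > 1L) for (k in seq_len(L - 1L))
    writeLines(paste(fmt(c(tr$mm[k], tr$mi[k], tr$md[k], tr$im[k],
                           tr$ii[k], tr$dm[k], tr$dd[k])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "sulfurCensus-profile v1")
    stop("not a sulfurCensus profile file: ", path)
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    sub(paste0("^", key, " "), "", ln)
  }
  L <- as.integer(kv("length"))
  bgLine <- strsplit(lines[startsWith(lines, "background")][1], "\t")[[1]]
  bg <- as.numeric(bgLine[-1])
  emStart <- which(lines == "emissions") + 1L
  E <- do.call(rbind, lapply(lines[emStart:(emStart + L - 1L)], function(x)
    as.numeric(strsplit(x, "\t")[[1]])))
  colnames(E) <- AA20
  trStart <- which(startsWith(lines, "transitions")) + 1L
  nm <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  if (L > 1L) {
    Tm <- do.call(rbind, lapply(lines[trStart:(trStart + L - 2L)], function(x)
      as.numeric(strsplit(x, "\t")[[1]])))
    tr <- setNames(lapply(seq_len(7), function(j) Tm[, j]), nm)
  } else {
    tr <- setNames(rep(list(numeric(0)), 7), nm)
  }
  # renormalize away the last-digit rounding of the text format
  E <- E / rowSums(E)
  bg <- bg / sum(bg)
  new("ProfileModel", family = kv("family"), matchEmissions = E,
      transitions = tr, background = setNames(bg, AA20),
      pseudocountWeight = as.numeric(kv("pseudocountWeight")),
      scoreCutoff = as.numeric(kv("scoreCutoff")),
      evdLambda = as.numeric(kv("evdLambda")),
      evdMu = as.numeric(kv("evdMu")),
      decoyCount = as.integer(kv("decoyCount")))
}

#' Accessors for ProfileModel
#'
#' @param x A \linkS4class{ProfileModel}.
#' @return \code{scoreCutoff}: the family bit-score cutoff;
#'   \code{profileLength}: number of match columns; \code{familyName}: the
#'   family identifier; \code{evdParams}: named vector (lambda, mu).
#' @export
scoreCutoff <- function(x) x@scoreCutoff

#' @rdname scoreCutoff
#' @export
profileLength <- function(x) nrow(x@matchEmissions)

#' @rdname scoreCutoff
#' @export
familyName <- function(x) x@family

#' @rdname scoreCutoff
#' @export
evdParams <- function(x) c(lambda = x@evdLambda, mu = x@evdMu)
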