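#' @useDynLib sulfurCensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats lm coef residuals rpois rlnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

# 20 standard amino acids, alphabetical one-letter codes; column order used
# by every emission matrix in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_AMBIG <- "X"
AA_GAPS <- c("-", ".")

# Robinson & Robinson (1991) amino-acid background frequencies, the standard
# null model for protein profile searches; renormalized to sum exactly to 1.
.RR_BACKGROUND <- c(
  A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
  F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
  K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
  P = 0.0482904, Q = 0.0395639, R = 0.0540978, S = 0.0683364,
  T = 0.0540687, V = 0.0673417, W = 0.0114135, Y = 0.0304133)

#' Amino-acid background distribution
#'
#' Robinson & Robinson residue frequencies over the 20 standard amino acids,
#' used as the null model for log-odds scoring, for emission pseudocounts,
#' and for sampling decoy and background protein sequences.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' sum(aminoAcidBackground())
aminoAcidBackground <- function() {
  bg <- .RR_BACKGROUND[AA20]
  bg / sum(bg)
}

# Encode a protein string as 1..20 indices; X -> 0 (scores as background).
# Any other symbol is an alphabet error.
encodeProtein <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty query sequence")
  idx <- match(chars, AA20)
  amb <- chars == AA_AMBIG
  idx[amb] <- 0L
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx) & !amb])
    stop("sequence contains symbols outside the protein alphabet: ",
         paste(bad, collapse = ", "))
  }
  as.integer(idx)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All stochastic operations in the package
# funnel through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible substream seed < 2^31 from a base seed and a label
# (iterated multiplicative hash; labels must map to distinct streams).
deriveSeed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ci in utf8ToInt(label)) h <- (h * 69069 + ci) %% 2147483647
  as.integer(h)
}

# Random protein sequence(s) at background composition.
randomProtein <- function(lengths, seed) {
  withSeed(seed, {
    vapply(lengths, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = aminoAcidBackground()),
            collapse = "")
    }, character(1))
  })
}

# Shared pairwise protein alignment settings (BLOSUM62, affine gaps).
.alnScore <- function(pattern, subject, type = "local") {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(pattern),
    subject = Biostrings::AAString(subject),
    type = type, substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
}

# Identity/coverage of the shorter sequence against the longer one, from a
# global-local alignment (shorter aligned end-to-end inside the longer).
# identity = matches / alignment columns; coverage = aligned residues of the
# shorter sequence / its length.
.pairIdentity <- function(a, b) {
  if (nchar(a) <= nchar(b)) { p <- a; s <- b } else { p <- b; s <- a }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(p), subject = Biostrings::AAString(s),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  c(identity = nm / width, coverage = (nm + nmm) / nchar(p))
}

# Distinct k-mer set of a protein string.
.kmers <- function(x, k = 5L) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, seq_len(n - k + 1L), seq(k, n)))
}

# Cheap prescreen: sequences ~95% identical over >=90% of the shorter must
# share a sizeable fraction of the shorter's 5-mers; unrelated random
# proteins share essentially none.
.kmerPrescreen <- function(kmA, kmB, shorterLen, k = 5L) {
  need <- max(1L, floor(0.2 * (shorterLen - k + 1L)))
  sum(kmA %in% kmB) >= need
}
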