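---
title: "Methods: a verifiable census of DMSP/DMS/MeSH cycling genes"
author: "sulfurCensus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a verifiable census of DMSP/DMS/MeSH cycling genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfurCensus)
```

## The scientific problem

Dimethylsulfoniopropionate (DMSP) is one of the most abundant organosulfur
molecules in the ocean; its catabolites dimethylsulfide (DMS) and
methanethiol (MeSH) link the marine sulfur cycle to microbial food webs and
atmospheric chemistry. A recurring question in environmental microbiology
is: *what fraction of a microbial community has the genetic potential to
synthesize or degrade DMSP?* The standard answer couples shotgun
metagenomics to profile-based homolog detection: assemble, predict genes,
build a non-redundant catalog with per-sample read counts, detect homologs
of the known DMSP/DMS/MeSH cycling families (dsyB, DSYB, mmtN for
synthesis; dmdA/dmdB/dmdC/dmdD for demethylation; the ddd lyases; mddA,
dmoA, ddhA, tmm and relatives for MeSH/DMS transformations), and normalize
each family's summed abundance by a universal single-copy marker — recA
for bacteria, beta-actin for eukaryotes — to express it as the percentage
of cells carrying the gene. Alongside the sequence census, DMSP standing
stock is measured chemically by alkaline lysis of DMSP to DMS and
headspace gas chromatography against a calibration curve.

This package implements that pipeline end to end as tested, reusable
code, together with a synthetic-community generator that provides ground
truth for every stage. The generator is not an afterthought: all
quantitative claims made by the test suite (estimator accuracy, decoy
false-positive control, taxonomic attribution) are claims about
communities it produced, so its design is documented here with the same
care as the estimators.

## Profile models and scoring

Each gene family is modeled as a Plan7-style profile built from an
alignment of ratified (functionally verified) positive sequences.

* **Match columns.** An alignment column becomes a match state iff its
  gap fraction is below 0.5 (majority occupancy). This is the standard
  construction convention; nothing in the pipeline is sensitive to the
  exact threshold for the ungapped synthetic training sets bundled here.
* **Emissions.** Observed residue frequencies blended with
  background-proportional pseudocounts; the pseudocount mass (default
  1.0 per column) prevents zero emissions for residues unseen in small
  training sets. The background is the Robinson–Robinson amino-acid
  distribution, the customary null for protein profile search.
* **Transitions.** Match/insert/delete transition probabilities are
  estimated per position from the gap structure of the alignment with
  Laplace (+1) pseudocounts. Two rare paths (insert entered from a
  delete, insert exited into a delete) are folded into the adjacent
  match-insert moves; with bundled (ungapped) training data these events
  never occur, and with gapped user alignments the approximation only
  smooths transition mass.
* **Scoring.** `scoreSequence()` returns the maximum log2-odds score over
  all local alignments: entry into any match state and exit from any
  match state are free, inserts emit at background (contribution 0), and
  the best path is found by Viterbi dynamic programming (compiled code).
  Local mode matters because metagenomic gene calls are frequently
  fragments. The ambiguity residue X scores exactly 0 at any match
  column, i.e. as background. The scorer is verified *exactly* against
  an independent brute-force enumeration of every legal state path for
  all model/query sizes up to 3x3 (over 200 random cases).

## Cutoffs and E-values

The families differ widely in conservation, so a single threshold is
inappropriate; each family gets its own cutoff derived from its training
data:

* leave-one-out (LOO) scores of each positive against a profile rebuilt
  from the others give the worst in-family score;
* negatives (sequences of different function) give the best out-of-family
  score;
* the cutoff is the midpoint of the two, falling back to `min LOO - 10`
  bits without negatives, and conservatively to `min LOO` (with a
  warning) when the training data are not separable. Ties are resolved
  upward because ambiguous candidates are meant to be removed, not kept.

Bit scores are converted to E-values through a Gumbel (extreme-value) fit
to the scores of i.i.d. background decoys, by the method of moments
(`beta = sd * sqrt(6) / pi`, `mu = mean - gamma * beta`). At a database
of size N, `E(S) = N * exp(-lambda * (S - mu))`. Method-of-moments is
adequate here: at 10,000 decoys the sampling error of both parameters is
well under 10% (tested), and the pipeline's marker cutoffs (E <= 1e-50
for recA, 1e-60 for beta-actin, reading "e-50" as 10^-50) sit so far in
the tail that any consistent fit gives the same verdict.

## Catalog construction

Contigs of 500 bp or less are removed (strictly greater-than 500
retained). Genes are clustered greedily at 95% identity over 90% of the
shorter sequence, processing genes by decreasing length so the founder —
and hence representative — of each cluster is its longest member.
Identity and coverage come from a BLOSUM62-scored global alignment of the
shorter sequence onto the longer (affine gaps 10/0.5): identity is
matches over alignment columns, coverage is aligned residues of the
shorter over its length. A 5-mer prescreen skips pairs that cannot reach
95% identity: two sequences >= 95% identical over >= 90% of the shorter
(length m) must share on the order of 0.7 m intact 5-mers, while
unrelated proteins share essentially none (expected < 0.1 for m ~ 300),
so requiring 20% of m is conservative by a wide margin. The greedy result
is verified against a prescreen-free all-pairs oracle.

Abundance is mapped reads divided by gene length (reads per base), with
gene-sample pairs under 2 mapped reads discarded. The discard is applied
per (gene, sample) pair; the alternative reading (summed across samples)
would let a deeply sampled site rescue a gene in a shallow one, which is
not how per-sample mapping filters behave. Note one deliberate
consequence: the discard floor is the only step of the chain that is not
invariant under rescaling a sample's counts, because a 1-read entry
crosses the floor when counts are multiplied. The scale-invariance
property is therefore exercised on communities whose counts sit far from
the floor.

## Verification and the census

Profile hits are candidates, not calls. Each candidate is re-aligned
(local BLOSUM62) against all positives and negatives of its family and
kept only if its best-scoring reference is a positive; exact ties are
removed. A gene hitting several families keeps only its best-scoring
family. Families lacking negatives fall back to cutoff-only acceptance
with a warning.

The census normalizes each family's summed verified abundance by the
domain marker's summed abundance (recA hits at E <= 1e-50 for bacterial
families; beta-actin at E <= 1e-60 for the eukaryotic families DSYB,
Alma1 and the TpMMT class — a fixed configuration shipped with the
package):

fraction(family, sample) = 100 * sum(abundance of verified family hits) /
sum(abundance of marker hits)

Because the marker is single copy, this ratio estimates the percentage of
that domain's *cells* carrying the family. Multi-copy families can
exceed 100%; values are reported unclamped with a warning rather than
truncated. Group summaries are arithmetic means over samples, excluding
(with a message) samples whose marker denominator is undefined.

An important subtlety the synthetic truth makes explicit: with unequal
genome abundances, "percentage of cells carrying the gene" is the
*abundance-weighted* carriage, not the fraction of distinct genomes. The
generator records both; estimator accuracy is measured against the
abundance-weighted value, which is the quantity the method actually
estimates. At equal abundances the two coincide.

## Taxonomic assignment

Genes are assigned by a lowest-common-ancestor (LCA) rule over their
reference-database hits, with MEGAN-style parameters: hits below 50 bits
are ignored, hits within 10% of the best bit score are retained, and the
gene is assigned to the LCA of the retained taxa (both parameters
configurable; a best-hit-only mode is available because the underlying
convention — best-hit filtering versus banded LCA — is genuinely
ambiguous in practice). Genes with no surviving hits are "unassigned",
tracked separately. Taxon abundance is a cumulative rollup (a node's
abundance includes its descendants), so domain totals plus the unassigned
pool conserve the table total exactly. Per-family genus rankings lift
species-level assignments to their genus and report above-genus
assignments under their own rank. The LCA implementation (pairwise
depth-walking) is verified exactly against an independent
root-path-intersection oracle on a ~190-node fixture taxonomy across 100
random hit sets.

## DMSP quantification

The chemical assay is modeled as: ordinary least-squares calibration of
instrument response against known DMS amounts (>= 3 distinct standards;
eight points in routine use), inversion of the line per replicate,
censoring of amounts below the 0.015 nmol headspace detection limit, and
division by sample mass (nmol per g; per L for seawater). No correction
for endogenous DMS is applied, so values mean "total DMSP plus endogenous
DMS" — the package reports them as such rather than pretending to a
separation the measurement cannot make. Replicates are summarized as mean
± sd over uncensored values. Cross-environment contrasts are ratios of
arithmetic means of per-site means, and sediment (per g) and seawater
(per L) values are never combined unless explicitly forced
(`unitBridge = TRUE`), because a mass-vs-volume ratio is qualitative at
best.

The packaged field table (per-site mean ± sd for three Yellow Sea and
four Bohai Sea sediment sites, five Okinawa Trough hydrothermal
sediment/polymetallic-sulfide measurements, and literature seawater
DMSPd/DMSPp values) reproduces the headline contrast: shelf sediments
carry about 5.4-fold more DMSP per gram than the hydrothermal group.
The same table supports a stronger published phrasing (~10-fold) only if
the two highest Yellow Sea sites alone are compared to the trough; the
packaged computation follows the arithmetic the full table supports.

## The synthetic-community generator

The generator emulates the features of real metagenomes the pipeline is
sensitive to, and records the truth it planted:

* **Abundances**: lognormal(0, sigma) relative abundances, default
  sigma = 1 — a heavy but realistic skew for marine communities; sigma = 0
  gives the equal-abundance limit used in exactness tests.
* **Markers**: exactly one recA per bacterial genome and one beta-actin
  per eukaryotic genome (enforced by the class validity).
* **Planting**: each family goes into exactly `round(f * n_domain)`
  genomes chosen by seeded shuffle. Deterministic planting separates
  planting noise from sampling noise, so small-n truths are exact.
* **Sequences**: per-family reference proteins are fixed, seeded random
  sequences; training positives are BLOSUM62-biased mutants at 15%
  divergence, planted genes at 30% (or at 15% from a genus-specific
  database variant when taxonomic signal is needed), markers at 10%,
  and background genes are random proteins with lognormal lengths
  (median 300 aa). Divergences above 60% are rejected as outside the
  validated range of the substitution-only mutation model.
* **Counts**: `counts(g, s) ~ Poisson(meanDepth * abundance * length /
  referenceLength)` independently per sample, with substream seeds
  derived from one base seed (named streams for taxa, abundances,
  planting, per-gene sequences, per-sample counts).

What the generator does *not* emulate — assembly chimeras, strain
microdiversity, uneven coverage along genes, sequencing error in protein
space, horizontally transferred partial genes — bounds what green tests
mean: they validate the statistical machinery and the detection logic
against clean homology at controlled divergence, not robustness to
assembler artifacts.

## Numerical and design choices

* All probability bundles are renormalized and checked to 1e-9 by class
  validity at construction and after calibration.
* The text profile format stores 12 significant digits; round-trip error
  is below 1e-11 and scores agree to 1e-9.
* Problem sizes in the test suite (200-genome communities for recovery,
  1,000 decoys per family, 100 LCA trials on a ~190-node tree, 3x3
  score-oracle cases) were chosen as the smallest sizes at which the
  statistical tolerances are meaningful.
* Verification tie-breaks, non-separable training sets, and fractions
  above 100% all resolve conservatively (remove / raise cutoff / warn),
  matching the pipeline's bias toward false negatives over false
  positives.
* The per-sample seed streams come from an iterated multiplicative
  string hash; a weaker positional hash produced colliding substreams
  (hence correlated samples) and was replaced.

## Known limitations

* The profile scorer is Viterbi-only (no forward-sum variant) and does
  not split multi-domain proteins; DNA-space (six-frame) search is out
  of scope.
* Candidate verification scales as hits x references and the reference
  aligner as genes x database; both are intended for catalog-scale
  inputs, not raw-read scale.
* Statistical comparison between environments (beyond descriptive
  ratios) is deliberately not implemented; the upstream convention does
  not name a test, and guessing one would imply rigor the data do not
  have.
* The E-value calibration assumes Gumbel tails for local alignment
  scores of i.i.d. background sequences; compositionally biased real
  proteins can inflate tail probabilities, which is why family cutoffs
  (not E-values) gate detection and E-values gate only the marker
  denominators, far from the calibration region.

## Example

```{r example, eval = FALSE}
tax <- makeSyntheticTaxonomy()
training <- syntheticFamilySet(c("DsyB", "RecA"))
profiles <- buildCalibratedProfiles(training, decoyCount = 200)

cm <- generateCommunity(100, c(DsyB = 0.3), tax, abundanceSigma = 0,
                        seed = 55)
catalog <- simulateCatalog(cm, meanDepth = 50 * 100)
hits <- searchCatalog(profiles, catalog$genes)
verified <- verifyCandidates(hits, catalog$genes, training)
tab <- computeAbundance(catalog$genes, catalog$counts)
communityFraction(tab, verified, "DsyB", "S01")  # ~30%
```
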