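# sulfurCensus

Who carries the genes that make and break dimethylsulfoniopropionate
(DMSP)? DMSP and its volatile catabolites DMS and methanethiol are
central to the marine sulfur cycle, and metagenomic surveys answer the
question by detecting homologs of the known cycling gene families
(synthesis: *dsyB*, *DSYB*, *mmtN*; demethylation: *dmdA–D*; lysis:
the *ddd* genes; MeSH/DMS transformations: *mddA*, *dmoA*, *ddhA*,
*tmm*, ...) in assembled gene catalogs and expressing each family as the
fraction of the community that carries it. `sulfurCensus` implements
that pipeline for R as tested, reusable components:

* **profiles** — per-family Plan7-style profile models built from
  ratified training alignments, scored by a compiled local Viterbi
  log2-odds algorithm, with leave-one-out/negative-midpoint score
  cutoffs and Gumbel E-value calibration on background decoys;
* **catalog** — contig length filter (> 500 bp), greedy 95%-identity /
  90%-coverage clustering with longest-member representatives, and
  reads-per-base abundance with the < 2-read discard;
* **census** — candidate verification against ratified positives vs
  different-function negatives, and single-copy marker normalization:

  `fraction(family, sample) = 100 · Σ abundance(verified family hits) /
  Σ abundance(marker hits)`

  with recA (E ≤ 1e-50) as the bacterial denominator and β-actin
  (E ≤ 1e-60) as the eukaryotic one;
* **taxonomy** — lowest-common-ancestor assignment over the top-score
  band of reference hits (MEGAN-style `minScore` 50 bits, `topFraction`
  0.10) and cumulative taxon-abundance rollups;
* **dmsp_assay** — headspace-DMS calibration lines, detection-limit
  censoring at 0.015 nmol, per-mass quantification, and
  cross-environment fold ratios (a per-site field table ships with the
  package);
* **synthetic_data** — a community simulator (lognormal abundances,
  exactly one marker per genome, deterministic family planting, Poisson
  read sampling) whose recorded ground truth makes every stage
  verifiable offline.

## Worked example

```r
library(sulfurCensus)

tax      <- makeSyntheticTaxonomy()
training <- syntheticFamilySet(c("DsyB", "RecA"))
profiles <- buildCalibratedProfiles(training, decoyCount = 200)

# 100 equal-abundance bacterial genomes, 30 carrying one dsyB
cm  <- generateCommunity(100, c(DsyB = 0.3), tax, abundanceSigma = 0,
                         seed = 55)
cat <- simulateCatalog(cm, meanDepth = 50 * 100)   # ~50 reads per gene

hits     <- searchCatalog(profiles, cat$genes)
verified <- verifyCandidates(hits, cat$genes, training)
tab      <- computeAbundance(cat$genes, cat$counts)
communityFraction(tab, verified, "DsyB", "S01")
#> [1] 30.09711
```

30.1% of the bacterial community is estimated to carry *dsyB* against a
planted truth of 30% — the residual is Poisson sampling noise at 50
reads per gene. On the packaged field table, the headline chemical
contrast:

```r
t1 <- loadFieldDmsp()
environmentRatio(t1, c("YS-sediment", "BS-sediment"),
                     c("OT-sediment", "OT-polymetallic-sulfide"))
#> [1] 5.391209
max(t1$dmspMean[t1$environment == "YS-sediment"])
#> [1] 72.2
```

i.e. shelf sediments hold ~5.4-fold more DMSP per gram than the
hydrothermal group, peaking at 72.2 nmol g⁻¹ in the Yellow Sea.

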