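Package: sulfurCensus
Title: Metagenomic Census of DMSP, DMS and MeSH Cycling Genes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects homologs of dimethylsulfoniopropionate (DMSP),
    dimethylsulfide (DMS) and methanethiol (MeSH) cycling gene families in
    protein gene catalogs using family-specific profile models with
    per-family score cutoffs and Gumbel E-value calibration, verifies
    candidates against ratified reference enzymes, normalizes gene
    abundances to the fraction of the bacterial (recA) or eukaryotic
    (beta-actin) community carrying each family, attributes genes to taxa
    by a lowest-common-ancestor rule, and quantifies DMSP standing stock
    from headspace-DMS calibration data. A synthetic-community simulator
    with recorded ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Sequencing, HiddenMarkovModel
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'assay.R'
    'catalog.R'
    'profiles.R'
    'census.R'
    'synthetic.R'
    'taxonomy.R'
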