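Package: dscoreR
Title: Disease-Specific Functional Scoring of Non-Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains disease/trait-specific models that assign every base of a
    genome a D-score, the probability that the base is associated with the
    disease or trait of interest. Risk variants from GWAS association
    catalogs form the positive set; a matched benign background (matched on
    distance to transcription start sites, or restricted to the vicinity of
    risk variants) forms the negative set at a 10:1 ratio. Fixed-width
    genomic windows are annotated with epigenomic read counts, binary
    genomic elements and conservation scores; informative features are
    selected by nonparametric two-sample tests with a cross-validated
    p-value threshold, and an ensemble of balanced classifiers is trained
    whose average vote is the D-score. Genome-wide score tracks support
    retrieval by variant identifier, by genomic region, and as region
    averages with genome-wide percentiles. Includes a synthetic-data
    generator for a toy genome so the whole pipeline can be exercised
    without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
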