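Package: pathgwas
Title: Gene-Set Association Testing on Individual-Level GWAS Genotypes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end gene-set (pathway) association analysis for
    case-control GWAS cohorts from individual-level genotypes: PLINK
    BED/BIM/FAM and GMT input, the standard sample/marker quality-control
    cascade (call rates, inbreeding, Hardy-Weinberg exact tests,
    case-control differential missingness, pairwise batch-effect scans,
    identity-by-descent relatedness pruning), ancestry principal components
    with Patterson normalization and Tracy-Widom component selection,
    covariate-adjusted single-marker logistic association, a self-contained
    phenotype-permutation set-based association (SBA) test with
    LD-independent top-SNP selection and max(T) family-wise correction, and
    a competitive gene-set test built on LD-aware gene statistics with
    adaptive permutation correction. Includes a structured case-control
    cohort simulator (Balding-Nichols population structure, founder-mosaic
    LD blocks, planted causal gene sets and QC artifacts) so every stage is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
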