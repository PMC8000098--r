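Package: rabbitGS
Title: Stochastic Simulation of Cost-Efficient Genomic Selection in Rabbit Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a maternal-line rabbit breeding program for litter size
    and evaluates genotyping/imputation strategies for single-step genomic
    selection. Provides a forward Wright-Fisher founder-genome generator with
    linkage disequilibrium, additive trait architectures, gene-drop meiosis
    through a multi-generation selection scheme, nested high/medium/low density
    SNP panels with per-role masking and genotyping-cost accounting, a
    pedigree-based phasing and imputation engine, pedigree BLUP and single-step
    GBLUP (H-matrix) evaluation, and selection-outcome metrics (imputation
    accuracy, genotype yield, gEBV accuracy, response to selection, percentage
    of correctly selected candidates).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
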