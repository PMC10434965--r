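Package: panelforge
Title: Design and Evaluation of Reduced SNP Panels for Population
    Assignment and Kinship Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving a reduced, population-informative SNP panel
    from dense genotyping-array data and for evaluating such a panel when it
    is re-genotyped by targeted capture sequencing. Implements genotype
    quality control (missingness, minor allele frequency, genotype-quality
    and depth masks, windowed r-squared linkage-disequilibrium pruning),
    principal components analysis and discriminant analysis of principal
    components (DAPC) with stratified cross-validated population assignment,
    marker selection from discriminant-axis contributions with capture-probe
    interval output, cross-platform genotype concordance with allele
    harmonization, target coverage profiling, off-target SNP classification,
    and structure-adjusted kinship estimation in the PC-Relate family with
    relationship-degree classification. A synthetic-data module simulates
    structured populations under the Balding-Nichols drift model with local
    linkage disequilibrium, Mendelian pedigrees, missingness, genotyping
    error and capture-sequencing depth/quality annotations, so the whole
    workflow is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: SNP, Genetics, PopulationGenetics, QualityControl,
    PrincipalComponent, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
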