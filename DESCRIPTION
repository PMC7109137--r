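Package: gapsel
Title: Genome-Assisted Parental Selection for Outbred Perennial Crops
Version: 0.1.0
Authors@R: person("Plant Breeding Analytics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating genome-assisted parental selection in
    two-generation breeding populations of outbred perennial crops.
    Implements pedigree (numerator) and VanRaden genomic relationship
    matrices, REML-fitted individual-tree mixed models with permanent
    environment effects (BLUP breeding values, progeny-based general
    combining ability, narrow-sense heritability), GBLUP genomic
    prediction with replicated k-fold cross-validation, SNP quality
    filters, and a gene-drop simulator of breeding populations with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    data.table,
    GenomeInfoDb,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
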