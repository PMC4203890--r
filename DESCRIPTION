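Package: subclonality
Title: Tumor Subclonal Deconvolution from Allele-Specific Copy Number and
    Somatic Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the segmental aneuploid genome proportion (sAGP) of
    somatic copy-number alterations from B-allele frequency and log R ratio
    signals under a regional two-way (euploid/aneuploid) mixing model, and the
    cancer cell fraction (CCF) of somatic point mutations under an exhaustive
    taxonomy of mutation-versus-CNA order and phase scenarios. Macroscopic
    clonal structure is characterized from the sAGP or CCF spectrum by
    comparing a uniform-plus-Gaussian model against a Dirichlet-process
    Gaussian mixture fitted by Gibbs sampling, with BIC model selection. A
    simulation module generates synthetic tumors with mixed-clone segments and
    scenario-constrained somatic read counts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
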