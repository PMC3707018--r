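Package: draftanchor
Title: Draft-Genome Anchoring, QC and Marker Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational stages used to build and validate draft plant
    genome assemblies: k-mer depth-distribution genome-size estimation and
    coverage reporting, read trimming and filtering, assembly summary
    statistics (N50, gap content), physical-map (sequence-tag) guided
    superscaffolding with AGP output, in-silico PCR validation of SSR and
    COSII markers with concordance classification, and perfect-unique probe
    placement with FPKM region quantification. Includes a deterministic
    synthetic-fixture generator so every stage is testable on planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
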