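Package: cas12fkit
Title: Amplicon Deep-Sequencing Analysis of Cas12f1 Genome Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies genome-editing outcomes from targeted amplicon deep
    sequencing of miniature Cas12f1 nuclease experiments in human and maize
    cells. Models protospacer-adjacent-motif (PAM) recognition and cut-site
    geometry, trims and aligns amplicon reads, extracts and left-normalizes
    insertion/deletion events, applies a 30-fold negative-control frequency
    filter, classifies diploid T0 plant zygosity from dual leaf-punch
    samples, enumerates candidate off-target sites genome-wide under
    mismatch and bulge limits, and screens candidate loci for putative
    edits. Includes seeded synthetic-data generators for every pipeline
    input so the full analysis is testable without deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    S4Vectors,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
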