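Package: orthocensus
Title: Orthogroup-Based Gene Censusing and Annotation Transfer Across
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative gene-annotation analysis for species with several
    genome assemblies. Reads OrthoFinder-style orthogroup membership tables,
    collapses protein-level membership to gene-cluster (locus) level,
    censuses gene clusters per assembly by the evolutionary breadth of their
    orthogroups, extracts candidate novel genes absent from a reference
    annotation, transfers ortholog descriptions from reference proteomes
    onto GFF3 transcript intervals, classifies transcripts as protein coding
    with a longest-ORF scan, and simulates multi-assembly gene-family
    datasets with planted duplication, missing-annotation, paralog-collapse
    and pseudogene events together with exact expected outputs for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
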