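Package: msimut
Title: Mutational Profiling of Microsatellite-Unstable Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the somatic mutational profiles of
    microsatellite-stable (MSS) and microsatellite instability-high (MSI-H)
    colorectal tumors from hotspot-panel sequencing. Provides a tabular
    cohort data model with MAF-like TSV and minimal VCF readers, an HGVS
    coding-variant parser with homopolymer and short-tandem-repeat context
    annotation of indels against reference coding sequences, per-tumor
    mutation-burden summaries with gene-set exclusion, rule-based MSI-H
    prediction with confusion-matrix evaluation, the PCR mononucleotide-locus
    assay call rule, frameshift neoepitope length arithmetic, exact and
    asymptotic 2x2 association tests, and a seeded synthetic-cohort
    simulator with run-length-dependent replication-slippage indels so the
    full pipeline is testable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
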