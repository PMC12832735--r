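Package: evcargo
Title: Extracellular Vesicle RNA Cargo Composition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of RNA cargo in extracellular vesicles (EVs) profiled
    by RNA-seq, qPCR arrays and hybridization count panels. Implements a
    rank-based cross-source comparison: per-feature mean log-abundance,
    top-K highly-represented sets per source, and gene-set (pathway)
    representation tables contrasting two cohorts. Also provides
    transcript-biotype composition summaries, read-mapping summaries,
    duplicate-Ct presence calling for qPCR arrays, negative-control
    background filtering for miRNA count panels, per-sample top-K
    recurrence, and a seeded negative-binomial study simulator with
    planted pathway enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
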