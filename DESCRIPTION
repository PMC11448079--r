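Package: mobilome
Title: Comparative Mobilome Analysis of Near-Identical Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the mobile-genetic-element content of two
    (or more) closely related bacterial genome assemblies. The package
    catalogues insertion-sequence (IS) elements against a reference library,
    discovers miniature inverted-repeat transposable elements (MITEs) de novo
    from structural criteria (terminal inverted repeats, target-site
    duplications, copy number, absence of a transposase open reading frame,
    stem-loop folding potential), links MITEs to a candidate mobilizing
    transposase family through shared termini, calls large inversions,
    strain-specific insertions and intra-genome duplications between two
    assemblies by unique k-mer anchoring, classifies the genic impact of each
    insertion difference (split coding products, reading-frame extension),
    overlays per-gene differential expression computed from TPM tables
    (Welch t-tests with Benjamini-Hochberg correction), and predicts in-silico
    PCR amplicon sizes. A deterministic synthetic genome-pair and expression
    generator with a machine-readable truth table makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
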