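Package: plastodecay
Title: Comparative Plastome Structure, Gene Degradation and Parsimony Analysis
Version: 0.1.0
Authors@R:
    person("plastodecay", "developers", email = "plastodecay@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative chloroplast genome analysis with a focus on
    progressive gene degradation. Detects the quadripartite plastome structure
    (LSC/IRa/SSC/IRb), computes composition statistics and codon usage,
    classifies genes as complete, pseudogenized, fragmented or deleted against
    a reference coding set, encodes the 22-character ndh presence/degradation
    matrix, scans microsatellites and long direct/palindromic repeats, computes
    alignment partition statistics (p-distance, parsimony-informative sites,
    divergence-hotspot ranking), and provides a maximum-parsimony engine with
    exact branch-and-bound search, strict consensus, consistency and retention
    indices, nonparametric bootstrap and ACCTRAN character-change mapping. A
    synthetic plastome generator with known ground truth (quadripartite
    structure, planted repeats, lesion recipes, Jukes-Cantor evolution along a
    known tree) makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    phangorn,
    jsonlite,
    rtracklayer,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
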