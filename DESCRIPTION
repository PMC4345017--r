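Package: srnapipe
Title: Characterization of Germline Small RNA Sequencing Libraries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the classification and characterization of
    small RNA deep-sequencing libraries from insect germline tissue. Covers
    3' adapter clipping, read collapsing, perfect-match genome mapping and
    reads-per-million normalization; annotation-category size profiling;
    de novo miRNA and mirtron discovery under duplex-overhang, 5'-homogeneity
    and multi-sample criteria; negative-binomial differential expression with
    chromosomal enrichment testing; and piRNA / endo-siRNA characterization
    (U1/A10 cluster calling, transposon strand bias, 29 to 27 size ratios,
    positional nucleotide-bias scoring, ping-pong diagnostics, 5' half-tRNA
    detection). A synthetic-data module plants every small RNA class with a
    machine-readable truth table so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
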