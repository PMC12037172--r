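Package: simpleomni
Title: Safe Contig Assembly with Simple Omnitigs on de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes maximal simple omnitigs -- overlapping, provably safe
    contigs -- from arc-centric de Bruijn graphs or abstract directed graphs.
    A simple omnitig is a walk with a non-branching core whose right part runs
    through out-degree-one nodes and whose left part runs through in-degree-one
    nodes; such walks extend classical unitigs through repeats and bubbles
    while remaining substrings of the underlying genome under an error-free,
    perfect-coverage model. The package provides unitig compaction, core
    detection and univocal extension in linear output-sensitive time, a
    brute-force enumeration oracle for testing, an executable safety verifier
    for linear multi-chromosome and circular genomes, EAxmax-style alignment
    contiguity metrics robust to overlapping contigs, a deterministic
    synthetic-genome generator with planted repeats and bubbles, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
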