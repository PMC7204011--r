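Package: dotprint
Title: Dot-Plot Fingerprints for Repeat Protein Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed self-similarity dot plots ("fingerprints") for protein
    sequences, binarized at a fixed black point, and tools built on them:
    a sliding Jaccard metric for comparing fingerprints of proteins of
    different lengths, repeat-protein classification from fingerprint
    information content, deconvolution of fingerprints into repeat residues
    and unit periods, in-silico substitution/insertion decay experiments
    with exponential decay fitting, alphabet-permutation Monte Carlo,
    consensus fingerprints for aligned protein families, hierarchical and
    Markov clustering of fingerprint collections, and a synthetic tandem
    repeat protein generator with ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
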