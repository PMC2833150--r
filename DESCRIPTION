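Package: loopwords
Title: Mining Recurrent Structural Words in Protein Loops with a
    Structural Alphabet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simplifies protein three-dimensional structures into strings
    of structural letters using a Gaussian-emission hidden Markov model
    over four inter-C-alpha backbone descriptors, segments the strings
    into regular secondary structures and loops, decomposes loops into
    overlapping short structural words, and characterises each word's
    fragment cluster: structural variability (Kabsch-superposed C-alpha
    RMSD), positional amino-acid Z-score profiles, loop-type preference
    (Kullback-Leibler divergence with a chi-square test), and statistical
    exceptionality against a first-order Markov background via exact
    pattern-automaton occurrence-count distributions with a
    compound-Poisson approximation for large corpora. Ships a synthetic
    data generator (Markov letter corpora with planted words, synthetic
    PDB structures, fragment sequences with planted positional
    preferences) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    BiocGenerics,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
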