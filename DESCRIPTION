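Package: tetrasieve
Title: Tetranucleotide-Signature Sieving of Genome Pairs for Species
    Demarcation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pre-selects candidate intraspecies genome pairs by comparing
    136-dimensional tetranucleotide z-value signatures, so that expensive
    whole-genome alignment (ANI/PSG) species demarcation only needs to run
    on a small fraction of all pairs. Implements genome pre-processing
    (short-sequence filtering, Naive-Bayes-ordered concatenation of draft
    assemblies), sliding-window fragmenting, representative-fragment
    z-value signatures (ZRF) with genome-specific and length-specific
    cutoffs, an all-vs-all sieve with a top-N rescue, a NUCmer delta
    parser with ANI and shared-genome (PSG) calculations, and a seeded
    Markov-mixture genome simulator for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
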