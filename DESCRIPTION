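Package: dnaflex
Title: Sequence-Determined DNA Mechanical Flexibility Analysis
Version: 0.1.0
Authors@R:
    person("dnaflex", "maintainers", email = "maintainers@dnaflex.dev",
           role = c("aut", "cre"))
Description: Genome-scale analysis of intrinsic DNA mechanical flexibility
    (loop-seq style cyclizability). Provides a trainable sequence-to-score
    regressor with reverse-complement averaging and a linear dinucleotide
    surrogate model, dinucleotide-preserving and distance-matched sequence
    shuffling null models, position-specific ("vertical") Markov samplers,
    transcription-start-site anchored metaprofiles, genome-wide
    actual-versus-shuffled flexibility scans, effect-size comparisons of
    flexibility at variant, methylation and protein-binding sites, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
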