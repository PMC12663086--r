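Package: oriforge
Title: Autoregressive Language Modeling and Constraint-Guided Design of
    Plasmid Replication Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for learning and designing plasmid origins of
    replication (oriVs). Replicons (host species label, Rep initiator
    protein(s), oriV nucleotide sequence) are tokenized into a mixed
    species/amino-acid/nucleotide vocabulary and modeled with a
    decoder-only autoregressive transformer trained by AdamW with early
    stopping. Trained models support conditioned sampling (nucleus,
    top-k) and constraint-guided beam search that provably avoids
    user-supplied restriction-site motifs on both strands, plus
    post-hoc infill repair of seed prompts. Companion modules provide
    identity-aware dataset splitting, teacher-forced next-nucleotide
    accuracy with bootstrap confidence intervals, in-silico validation
    metrics (AT content, sliding-window folding energy, PWM motif
    scanning), affine-gap global alignment with matched random-mutant
    controls, pooled-competition fitness statistics, and a synthetic
    replicon-corpus generator with planted, verifiable sequence
    elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
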