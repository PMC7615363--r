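Package: quasipool
Title: Quasispecies Sequence-Pool Analysis for Aptamer Selections from
    Homopolymeric Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse in vitro selection (SELEX) campaigns that start
    from a single, partially homopolymeric seed sequence and diversify it by
    error-prone replication. Provides sequence-pool input/output with primer
    trimming and abundance collapsing; a stochastic quasispecies simulator
    (substitutions with a transition/transversion bias, indels, homopolymer
    slippage, truncation bias and template-switching recombination, followed
    by motif-biased selection); Damerau-Levenshtein pool-diversity measures
    with a random-pool baseline and per-position mutation rates; degenerate
    (IUPAC) loop-motif scanning and a structural descriptor parser/matcher
    (helices plus strands); secondary-structure energy profiles through an
    external minimum-free-energy engine or a built-in base-pair-maximisation
    fallback; one-hot sequence encoding with round-wise 2-D embeddings; and
    a one-site isothermal titration calorimetry binding model with
    simulate-and-recover fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
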