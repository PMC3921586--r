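Package: kznfevo
Title: Evolution of KRAB Zinc-Finger Repressors and Their Endogenous Retrovirus Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how clusters of KRAB-associated C2H2 zinc-finger
    genes arise by tandem duplication and come to silence endogenous retroviruses
    (ERVs). The package scans genomic DNA for C2H2 zinc-finger motifs by six-frame
    translation, groups them into tandems, dates duplications with Jukes-Cantor
    corrected divergence and UPGMA trees, quantifies transposable-element enrichment
    of repressor ChIP peaks against an accessible-chromatin null, estimates regional
    deletion rates from the frequency spectrum of polymorphic deletions (Watterson
    and a frequency-spectrum refinement), predicts zinc-finger tandem binding of
    ERV-family-specific motifs through a pluggable recognition code, and tests
    whether repressors contemporaneous with their target family's invasion are
    enriched on chromosome 19 (Fisher's exact test, with a noisy-classifier
    bootstrap correction). A seeded synthetic-data module generates every input
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
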