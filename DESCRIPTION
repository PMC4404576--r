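Package: mirenrich
Title: miRNA Target Over-Representation in Gene Lists and ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether conserved miRNA-family targets are over-represented
    in a gene set, where the set is given directly or derived from ChIP-seq
    peak files. The test draws random gene sets from a TargetScan-style
    prediction background and compares per-family target counts after a
    scaling correction that neutralises gene-set-level confounders such as
    average 3'UTR length, then adjusts the Monte-Carlo p-values with the
    Benjamini-Hochberg procedure. Includes nearest-TSS and ranked
    promoter/first-intron peak-to-gene association, detection of
    transcription-factor/miRNA feedforward and feedback loops around a master
    regulator, and a synthetic-fixture generator for all input tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
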