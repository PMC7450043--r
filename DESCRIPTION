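Package: nascentFRET
Title: FRET Analysis of Cotranslational Folding in Ribosome-Nascent-Chain
    Complexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for solution FRET measurements of stalled
    ribosome-nascent-chain complexes, as used to monitor cotranslational
    compaction of the CFTR first nucleotide-binding domain (NBD1). Converts
    matched four-reaction experiments (donor, donor+acceptor, and their
    non-fluorescent blanks) from raw CFP emission spectra and 14C
    scintillation counts into FRET efficiencies via donor quenching, with
    amber-suppression readthrough quality control. Aggregates replicates
    into length-dependent compaction profiles, folding-window detection,
    ribosome bound-versus-released contrasts, thermal-denaturation
    difference curves, and immunoblot-based maturation quantification. A
    synthetic-data generator emulates the assay's generative process
    (stalled chains, readthrough mismatch, counting noise) with closed-form
    oracles so every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
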