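Package: lipoprospect
Title: Degenerate Consensus-Primer Design and Enzyme Characterization for
    Bacterial Lipase Prospecting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for PCR-based prospecting of bacterial lipase/esterase
    genes and downstream biochemical characterization. Implements an algebra
    of IUPAC-degenerate nucleotide sequences (expansion, complementation,
    pattern matching, translation), back-translation of conserved protein
    motifs into fully degenerate consensus primers with restriction-site
    tails, conserved-block discovery and length-based cluster splitting in
    pre-aligned protein families, two-factor central composite designs with
    second-order response-surface fitting (pure-error and lack-of-fit ANOVA,
    stationary-point analysis), Michaelis-Menten and Hill kinetics with an
    interfacial-activation screen, activity-profile and thermal-stability
    summaries, and seeded synthetic-data generators so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
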