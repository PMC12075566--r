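Package: metscreen
Title: Pharmacophore Screening and Hit Triage for MET Channel Modulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening and hit-triage toolkit for
    modulators of mechano-electrical transduction (MET) channel pores such as
    TMC1. Implements 3D pharmacophore feature perception from molecular
    graphs, common-pharmacophore hypothesis generation and ranking, two-pass
    pharmacophore matching (RMSD gate plus screen score), total screen-score
    aggregation with a mean-plus-two-standard-deviations docking threshold,
    decoy-based model validation (ROC/AUC and the Guener-Henry metric
    family), Morgan-fingerprint Tanimoto clustering for diversity-aware
    representative selection ranked by binding energies, per-residue
    docking-pose contact-frequency analysis with interaction typing, and
    HOLE-style pore-radius profiling of channel structures. Ships seeded
    synthetic-data generators with analytic ground truth for every stage and
    a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    ChemmineR,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
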