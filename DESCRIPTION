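Package: cox2qsar
Title: QSAR Modelling and Ligand Triage for COX-2 Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and validates multiple-linear-regression QSAR models of
    COX-2 inhibitory activity (pIC50) from pharmacophore descriptor counts:
    Pearson-correlation descriptor selection, exhaustive descriptor-subset
    enumeration with a ranked model leaderboard, residual-based internal and
    external validation, and prediction of candidate activities. Also provides
    the desk-scale ligand-triage arithmetic used in structure-based screening
    campaigns: Tanimoto similarity on binary fingerprints, paired-atom RMSD,
    Lipinski rule-of-five violation counting, binding free energy from
    inhibition constants, and MM-GBSA energy-term aggregation with per-residue
    decomposition. Ships the published training, validation and candidate
    tables of a rofecoxib-analogue COX-2 screening study as plain-text
    fixtures, plus synthetic-data generators that emulate their statistical
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
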