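Package: hdxprodyn
Title: Hydrogen/Deuterium Exchange Mass Spectrometry Analysis of Protein
    Structure Dynamics
Version: 0.1.0
Authors@R:
    person("HDX", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for peptide-level hydrogen/deuterium exchange (HDX)
    mass spectrometry: intensity-weighted centroiding of isotopic clusters,
    back-exchange-corrected deuterium uptake, differential (apo versus
    ligand-bound) statistics with paired t-tests over the late exchange
    timepoints, projection of protection onto residues and a PDB structure
    via the B-factor column, and comparison with multiple-sequence-alignment
    conservation.  Includes a first-order-kinetics simulator of complete
    synthetic HDX experiments (isotopic envelopes from exact elemental
    composition, Poisson-binomial deuterium distributions, multiplicative
    intensity noise) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
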