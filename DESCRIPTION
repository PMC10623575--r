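Package: lripscreen
Title: Function-Based Ligand Screening via Ligand-Residue Interaction Profiles
Version: 0.1.0
Authors@R:
    person("LRIP", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes ligand-residue interaction profiles (LRIPs) from
    receptor-ligand conformational ensembles by MM-GBSA-style per-residue
    free-energy decomposition (Coulomb, Lennard-Jones, Hawkins generalized-Born
    polar solvation, Shrake-Rupley solvent-accessible surface area), builds
    agonist/antagonist signature profiles from reference ligands, scores
    profile similarity (R, R2, RMSE, AUE, ASE), and classifies compounds as
    agonists versus non-agonists with a correlation-and-binding-energy decision
    rule (R > 0.84, dE < -10 kcal/mol).  Includes seeded synthetic toy-complex
    and correlated-profile generators, packaged evaluation fixtures, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
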