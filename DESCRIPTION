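Package: resistrank
Title: Biophysics-Based Ranking of Target-Site Mutations for Herbicide
    Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores protein-ligand complexes of a herbicide target enzyme
    (wild type and point-mutated) with single-structure implicit-solvent
    binding free energies (MM-PBSA/GBSA-style: pairwise electrostatics and
    Lennard-Jones interaction terms, generalized Born OBC/GBn, ALPB and
    finite-difference Poisson-Boltzmann polar solvation, and a solvent
    accessible surface area nonpolar term), ranks variants from weak to
    strong binding, and classifies resistance with accuracy, enrichment
    factor and ROC-AUC metrics, paired-t method comparison, and a
    class-imbalance sensitivity resampling. Includes in-silico side-chain
    grafting with clash-relief minimisation, PQR structure input/output,
    a curated Kochia scoparia acetohydroxyacid synthase mutation panel,
    and synthetic pocket-complex and affinity-table generators for
    end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
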