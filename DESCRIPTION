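Package: tmrscape
Title: Consensus and Conformational-Landscape Analysis of Transmembrane Hairpin Bundles
Version: 0.1.0
Authors@R:
    person("TMR", "Maintainers", email = "tmrscape@example.org", role = c("aut", "cre"))
Description: Tools for comparing predicted structural models of membrane-embedded
    four-helix (two-hairpin) bundles and for analysing their conformational
    dynamics. Provides PDB and PAE-JSON readers with per-residue confidence
    (pLDDT) handling, Kabsch superposition and pairwise RMSD matrices,
    inter-helix distance/contact maps with interface classification,
    membrane-ejection quality control of trajectories, joint PCA/TICA
    conformational embeddings, PAM-style K-medoids clustering with elbow
    selection and per-cluster contact fingerprints, plus a seeded synthetic
    bundle/trajectory generator that plants known contact architectures,
    Ornstein-Uhlenbeck fluctuations, state switching and irreversible
    membrane-ejection events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
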