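Package: hingedock
Title: Structure-Based Virtual Screening with a Solvent-Contact Desolvation Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Desk-scale structure-based virtual screening toolkit for
    ATP-competitive kinase inhibitor discovery. Implements an empirical
    protein-ligand binding free energy function with five weighted terms
    (12-6 van der Waals, angle-weighted 12-10 hydrogen bond, sigmoidal
    distance-dependent dielectric electrostatics, rotatable-bond entropy
    penalty, and a Gaussian solvent-contact ligand dehydration term),
    rule-based receptor protonation and hydrogen placement, precomputed
    affinity grid maps with genetic-algorithm pose search, a two-step hit
    filtration pipeline anchored on a hinge-region hydrogen bond, and
    core-fixed de novo derivative growth. Ships a synthetic fixture
    generator and an independent brute-force energy oracle so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel, optional; needed only for SMILES
    input and 3D embedding)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
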