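Package: catfield
Title: Catalytic Fields and Differential Transition-State Stabilization for
    Enzyme Mechanism Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse enzyme reaction mechanisms through atomic
    multipole electrostatics. Implements cumulative atomic multipole moment
    (CAMM) interaction energies via Cartesian interaction tensors (rank 0-4
    moments, R^-5 truncation), differential transition-state stabilization
    (DTSS) energies of environment residues, static catalytic-field grids
    mapping where a unit charge lowers the activation barrier, barrier
    estimates from per-residue DTSS contributions, and the MULTISCAN
    combinatorial search over side-chain rotamer conformations. Includes
    rigid-body superposition, conserved-charged-residue detection from
    multiple alignments, side-chain flexibility statistics, readers and
    writers for multipole, rotamer-library, PDB, Gaussian cube and report
    formats, and deterministic synthetic-fixture generators with a
    brute-force Coulomb oracle so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
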