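Package: mvatkit
Title: Oligomer Assembly, Interface Analysis and SEC-SAXS Tools for
    MvaT-Family Nucleoid-Associated Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural computations for studying the oligomerization of
    MvaT-family nucleoid-associated proteins (the Pseudomonas analogs of
    H-NS). Provides rigid-body Kabsch superposition and RMSD analysis,
    chimeric monomer splicing and terminal-site filament propagation,
    dimer-interface characterization (Shrake-Rupley solvent-accessible
    surface area, buried interface area, salt bridges, hydrophobic
    contacts), SEC-SAXS solution-structure analysis (frame reduction,
    Guinier and normalized Kratky analysis, Debye theoretical profiles
    and profile fitting), conservation mapping of interaction residues
    onto multiple sequence alignments, and synthetic-structure and
    synthetic-scattering generators with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'structio.R'
    'superpose.R'
    'assembly.R'
    'saxs.R'
    'synthetic.R'
    'conservation.R'
    'interactions.R'
    'cli.R'
    'mvatkit-package.R'
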