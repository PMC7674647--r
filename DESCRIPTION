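Package: ppgpp
Title: Conformational and Interaction Analysis of (p)ppGpp Alarmone Nucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural analysis toolkit for the bacterial alarmone
    nucleotides ppGpp and pppGpp. Computes glycosidic and backbone torsion
    angles, ribose pseudorotation parameters (phase angle P, puckering
    amplitude nu_max) and sugar pucker classes from PDB-format coordinates;
    detects and types non-covalent ligand-protein contacts (hydrogen bonds,
    weak hydrogen bonds, van der Waals contacts and clashes, ionic, metal
    coordination, aromatic stacking, polar and weak polar) with explicit
    geometric criteria; aggregates contact fingerprints per atom, per
    moiety and per functional protein class; and provides conformer
    ensemble descriptors (RMSF, radius of gyration, solvent accessible
    surface area, intramolecular hydrogen bonds). A synthetic-structure
    generator builds guanine nucleotides at prescribed conformations and
    toy binding sites with planted contacts, so the whole pipeline is
    testable without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
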