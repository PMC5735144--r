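Package: iebind
Title: Interaction-Entropy and MM/PBSA-Style Binding Free Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-point binding free energy analysis for protein-ligand
    complexes from molecular dynamics snapshots. Computes per-frame
    Coulomb and Lennard-Jones protein-ligand interaction energies, the
    interaction-entropy (IE) estimate of -T*dS by exponential averaging
    of energy fluctuations, solvent-accessible surface area (Shrake-Rupley)
    and the linear nonpolar solvation term, and assembles MM/PBSA-style
    free energy breakdowns under single- and triple-trajectory schemes
    with snapshot-group standard deviations. Includes trajectory stability
    diagnostics (superposed backbone RMSD, B-factors, hydrogen-bond
    occupancy, fractional native hydrogen bonds), per-residue
    decomposition of the interaction energy, readers and writers for
    multi-model PDB, plain coordinate tables and energy series, and a
    seeded synthetic-data generator so every stage can be exercised
    without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
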