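Package: radmotor
Title: Targeted Molecular Dynamics and Dihedral-Rotation Analysis of
    RecA-Family Filament Conformational Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for studying conformational transitions of
    RecA-family (RadA/Rad51) nucleoprotein filaments. Provides a targeted
    molecular dynamics (TMD) engine that drives a coarse-grained
    elastic-network filament model between reference conformations with a
    harmonic best-fit RMSD restraint on a decreasing target-RMSD schedule;
    per-residue backbone phi/psi time series with angle unwinding and the
    cumulative changed dihedral angle (CCDA) winding statistic; rotary versus
    zero-rotary residue classification for the RadA linker region; PDB
    structure and multi-model trajectory input/output; synthetic helical
    filament and programmed dihedral-rotation generators with known ground
    truth; and pairwise sequence identity via global alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
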