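Package: espath
Title: Early-Stage Protein Folding Geometry and Amyloid Transformation Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of polypeptide backbones in the early-stage
    (ES) protein-folding model. Computes backbone dihedral angles from PDB
    files, characterises Ramachandran space by the V angle between
    consecutive peptide-bond plane orientations and the radius of curvature
    R of the projected C-alpha trace of alanine pentapeptides, derives the
    elliptical early-stage path in the Phi-Psi plane from the parabolic
    ln(R)-versus-V relation, projects arbitrary conformations onto it
    (Phie/Psie), classifies per-residue conformations into the amyloid
    structural-code alphabet (AB, R, L, B, M with beta sub-zones E and F),
    and generates stepwise morphing trajectories from native toward
    amyloid-like conformations with full 3D backbone reconstruction from
    torsion angles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
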