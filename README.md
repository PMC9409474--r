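# espath

Geometric analysis of polypeptide backbones in the early-stage (ES)
protein-folding model, and stepwise morphing of native fragments toward
the flat, beta-dominated conformation of amyloid chains.

Amyloid fibrils stack essentially two-dimensional polypeptide chains
whose hydrogen bonds all point perpendicular to the chain plane. That
flatness is achieved by torsion angles concentrating on the line
Psi = -Phi of the Ramachandran plot (with Phi < 0, Psi > 0), interrupted
by single residues in right- or left-handed helical conformation that
twist the hydrogen-bond dipoles while keeping the chain flat. espath
provides the geometric toolkit behind this picture, for structural
bioinformaticians studying amyloid transformation:

* **V angle** — the angle between consecutive peptide-bond plane
  orientations (directed by the C=O bond): 0 in the idealised helical
  limit, 180 in the antiparallel beta limit.
* **R, radius of curvature** — radius of the circle fitted to the
  C-alpha trace of a homogeneous alanine pentapeptide projected in a
  common frame whose Z axis is the mean carbonyl direction; ln R grows
  from ~0.8 at the alpha-helix (R = 2.27 A) toward a capped sentinel in
  the rectilinear beta limit.
* **The elliptical early-stage path** — derived from the parabolic
  dependence of ln R on V over the low-energy regions of the
  Ramachandran map, the one-dimensional conformational subspace assumed
  for backbone-only folding intermediates. Conformations are projected
  onto it by shortest distance, giving (Phie, Psie).
* **Structural codes** — per-residue classification into AB (amyloid
  beta, on/near Psi = -Phi), R/L (helical), E/F (rectilinear/twisted
  beta), M (between basins), with per-class dispersion statistics.
* **Morphing** — the stepwise procedure moving a fragment from its
  native torsions to an amyloid target: approach the ellipse, travel
  along it, then finish exactly on the Psi = -Phi line (or into the
  L-helical basin), with every frame rebuilt in 3D.

## Worked example

```r
library(espath)

## the derived early-stage path shipped with the package
e <- default_ellipse()
e
#> ellipse_path: center (-2.65, -1.67), semi-axes (181.04, 84.84),
#>   tilt -45.89 deg [derived: rv_map step=5, ...]

## project the right-handed helix point onto it
project_to_ellipse(-57, -47, e)
#>     phie   psie distance      t
#> 1 -67.36 -56.76    14.23 268.26

## V and R at the two ends of the path
p <- orient_common_frame(build_pentapeptide(-57, -47))
c(V = compute_V(p), R = compute_R(p)$R)
#> V: 23.13   R: 2.27        # helical: near-parallel carbonyls, tight circle
pab <- orient_common_frame(build_pentapeptide(-135, 135))
c(V = compute_V(pab), R = compute_R(pab)$R)
#> V: 175.38  R: 7.95        # Psi = -Phi: antiparallel, rectilinear

## classify and morph a 25-residue helical fragment to the amyloid line
zc <- zone_config()
start  <- dihedral_series(11:35, rep(-57, 25), rep(-47, 25))
target <- dihedral_series(11:35, rep(-135, 25), rep(135, 25))
tr <- morph_fragment(start, target, e, zc)
ab_count(tr, zc)
#> [1]  0  0  0  0  0  0 25 25 25 25   # AB residues per frame, 10 frames
render_trajectory(tr, "morph_out")    # frame_000.pdb ... frame_009.pdb
```

The projection distance (14.23 degrees) is the helix zone's offset from
the derived path; the AB counts show the whole fragment reaching the
amyloid line in the terminal stage and holding it to the final frame.

A command-line wrapper covers the same pipeline
(`inst/scripts/espath`): `dihedrals`, `rvmap`, `project`, `classify`,
`stats`, `compare`, `mutations`, `morph`, `build`, `fixtures`, all
emitting TSV with provenance headers.

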