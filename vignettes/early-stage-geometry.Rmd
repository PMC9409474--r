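---
title: "Backbone geometry of the early-stage folding path and amyloid morphing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone geometry of the early-stage folding path and amyloid morphing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espath)
```

## The model

espath implements a geometric model of the polypeptide backbone in which
the conformation of a chain fragment is summarised by two quantities
derived from a homogeneous alanine pentapeptide built at each (Phi, Psi)
point of the Ramachandran map:

* **V** — the angle between consecutive peptide-bond plane
  *orientations*, in degrees in [0, 180];
* **R** — the radius of curvature of the pentapeptide's C-alpha trace
  projected on the XY plane of a common frame, reported as ln R.

The model's premise is that a backbone-only folding intermediate (the
"early stage", before side-chain interactions dominate) is confined to a
one-dimensional subspace of the Ramachandran plot: an ellipse passing
through the right-handed helical basin, the left-handed basin, and the
beta field around the line Psi = -Phi. Projecting any conformation onto
this path by shortest distance yields its early-stage coordinates
(Phie, Psie). A stepwise morphing procedure then moves a native fragment
along the path into the flat, Psi = -Phi-dominated conformation
characteristic of amyloid chains.

## The V angle is directed

A subtlety worth stating prominently: V is computed between *directed*
plane orientations, each peptide unit being represented by its C->O bond
direction. The planes themselves are nearly coplanar in beta structure,
yet beta is the V = 180 limit — because the carbonyl (and with it the
hydrogen-bond dipole) flips from unit to unit. Helical structure keeps
the carbonyls parallel (V = 0 in the idealised limit; about 23 degrees
for the real alpha-helical geometry). An undirected plane-normal variant
is available via `compute_V(..., method = "normal")`, but all shipped
defaults use the directed definition, which reproduces the printed
limits. V is averaged over the pentapeptide's three consecutive plane
pairs; `pairs = "central"` switches to the middle pair only.

## The common frame and the beta limit of R

The frame is fixed by the mean C->O direction over *all* carbonyl groups
(Z axis), the C-alpha centroid (origin), and the XY projection of the
first-to-last C-alpha displacement (+X; R and V are invariant to this
last rotation, which only standardises coordinates). Using all five
carbonyls rather than the four peptide-bond units is deliberate: near
Psi = -Phi the chain has an almost exact two-fold screw, consecutive
carbonyls cancel pairwise along the screw axis, and a four-unit mean
degenerates onto that axis — the projection then collapses to the local
pleat circle and R would *shrink* toward beta. The odd terminal carbonyl
keeps the frame off-axis, the projected trace stays rectilinear, and the
fitted R grows monotonically along the Psi = -Phi band toward the
extended limit, which is the behaviour the model requires.

R is an algebraic (Kasa) least-squares circle through the five projected
C-alpha points. Two degeneracies are capped at R = 1e6 A (ln R ~ 13.8):
a projected trace collinear within a smallest-singular-value tolerance
of 1e-3 A, and a mean-carbonyl norm below 0.1 (an ill-conditioned
frame). The infinite beta radius thus becomes a finite, plottable
sentinel carried in the `capped` flag; capped points are excluded from
all fits. The alpha-helix value, R ~ 2.27 A, is the C-alpha cylinder
radius of the helix, as it should be.

Covalent geometry uses standard single-conformer restraint values
(N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A; N-CA-C 111.2,
CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 degrees; trans peptide bonds).
All are overridable through `geometry_params()`.

## Deriving the elliptical path

`generate_rv_map(step = 5)` evaluates V and ln R on the 72 x 72 grid.
`fit_parabola()` fits ln R = c2 V^2 + c1 V + c0 by least squares over
grid points inside the low-energy mask (and not capped): the parabola
expresses the *relaxed* radius expected at a given V.
`derive_ellipse()` then selects the relaxed points — inside the mask,
not capped, |ln R - parabola(V)| <= 0.5 — and fits a direct
least-squares conic constrained to an ellipse (Fitzgibbon).

Two derivation choices deserve justification:

* **The selection is restricted to the low-energy mask.** The
  parabola-agreement band alone is a two-dimensional swath covering most
  of the map (the surface simply is that flat in ln R), and an ellipse
  fitted to it is near-circular and misses the helical zones entirely.
  Restricting to the mask links the basins into the expected closed
  path. The mask is four inversion-symmetric rectangles (the
  right-handed helical core, its inversion, the beta core, and its
  inversion) shipped as explicit polygons in `zones-default.yaml`.
* **The derived parameters are frozen.** The shipped
  `ellipse-default.yaml` records the result of the step-5 derivation —
  center (-2.65, -1.67), semi-axes (181.0, 84.8), tilt -45.9 degrees —
  plus its provenance, and `default_ellipse()` reads it. A test
  re-derives the path and must reproduce the frozen values, so the
  config cannot silently go stale. Users may substitute explicit
  parameters; published descriptions of this path exist only
  pictorially, so the derived default is the package's own reproducible
  stand-in and numbers depending on the exact path carry tolerances.

The default path passes within ~14 degrees of (-57, -47), ~8 of
(57, 47), and crosses Psi = -Phi at (-128.5, 128.5) and its inversion.
Along the arc from the helical zone to the beta crossing, V rises
monotonically; ln R dips through the compressed-helix flank before its
radical increase into beta — a genuine feature of constrained helix
unwinding, not an artifact, and the reason the package asserts
end-above-start rather than pointwise monotonicity for ln R.

## Projection

`project_to_ellipse()` minimises Euclidean distance in degrees over the
ellipse parameter, per periodic image of the query (all nine +/-360
shifts; the Ramachandran space is a torus), with a 2-degree coarse scan
refined by safeguarded Newton iterations on the distance derivative.
Ties break toward smaller parameter t. Tests hold it within 0.05 degrees
of an exhaustive 0.01-degree sampling oracle.

## Structural codes and dispersions

Zones are explicit polygons (versioned YAML), drawn to the classical
basins: R (phi in [-180, -20], psi in [-120, 30]), L its inversion, the
beta field (phi in [-180, -20], psi in [60, 180]) and an M band between
R and beta. Codes in precedence order: AB (beta field, phi < 0, psi > 0,
within 15 degrees of Psi = -Phi by perpendicular distance), R, L, E
(beta within the 30-degree band of the line), F (remaining, twisted
beta), M, other. The band widths are tunable; 15 degrees for AB and 30
for E were chosen once from the scale of dispersions a flat amyloid
chain must maintain, and are not calibrated against any particular
structure. For dispersion reports the E class includes the AB core (the
beta-area statistic measures concentration around the line), so
count(E+F) = count(E) + count(F) holds by construction. Helical
dispersions are mean distances to the per-structure class centroid,
computed without periodic unwrapping — the helical basins sit well
inside one period.

## Morphing toward the amyloid form

`plan_path()` builds a per-residue piecewise path: straight to the
residue's (Phie, Psie); along the ellipse (monotone in t) toward the
target's projection; then a terminal stage by target code. AB targets
leave the ellipse at its Psi = -Phi crossing and continue *exactly* on
the line (waypoints satisfy phi + psi = 0 to machine precision; the
final step lands on the target itself, which may sit slightly off the
line). L targets ride the arc into the left-handed basin and finish
straight; all other targets go straight from the arc exit. The default
arc is the shorter one; `constrained = TRUE` selects the complementary
arc through the compressed-helix flank, for residues whose chain context
prevents free unwinding. Straight segments interpolate linearly with
periodic-aware shortest angular displacement per coordinate.

`morph_fragment()` executes the plans synchronously — every residue
advances one waypoint per frame, so a trajectory has 1 + sum(steps)
frames regardless of fragment length; stationary residues are never
perturbed. The default steps (3, 3, 3) give 10 frames, matching the
granularity at which such transformations are usually displayed.
`render_trajectory()` rebuilds each frame in 3D via the torsion-space
builder and writes numbered PDB files.

## Backbone reconstruction

`build_backbone()` is the exact inverse of `compute_dihedrals()` up to
the fixed covalent geometry: sequential natural-extension placement from
a canonical first-residue frame (N at origin, CA on +X, C in the XY
plane), carbonyl O in the peptide plane anti to the next N, OXT not
modelled, omega trans unless overridden per residue. The in-memory
round-trip dihedrals -> backbone -> dihedrals is exact to 1e-6 degrees;
through a PDB file the format's 0.001 A coordinate precision limits
torsion agreement to ~0.02 degrees, and file-based tests assert 0.05.

## Synthetic data, and what the tests do not show

All fixtures are generated in code: ideal conformers and motif chains at
the zone representatives, seeded Gaussian jitter (`make_noisy`), and a
native/amyloid stand-in pair (`make_synthetic_pair`) whose amyloid
member concentrates on Psi = -Phi (sigma 6 degrees) with isolated
helical residues, versus a broadly scattered native member (sigma 18).
These reproduce the *class structure* of the real comparison — tight
amyloid dispersions, internal count consistency, R-to-AB migrations —
but none of the crystallographic reality of particular deposited
structures: no missing fragments, no alternate conformations, no real
beta-sheet twist statistics. Quantitative reproduction of the published
per-structure dispersion table therefore requires the four transthyretin
entries (1DVQ, 1GKO, 1G1O, 6SDZ), which `scripts/fetch_structures.R`
downloads when network access is available; the corresponding test
blocks report their absence otherwise. Zone boundaries are pictorial in
the source literature, so even with the real entries the class counts
are tolerance targets, not bit-exact ones.

## Problem sizes and numerical choices

The shipped derivation uses the full 5-degree map (5184 pentapeptides,
~13 s); routine tests use 20-90 degree grids. The projection oracle
comparison runs 10^4 random queries. Degenerate inputs are explicit
errors, never silent: chains shorter than two residues, empty series,
coincident projected points, a vanishing mean carbonyl direction,
non-divisor grid steps, conic fits that degenerate to non-ellipses.
Determinism is part of the contract: same inputs and configs give
byte-identical outputs, and every CLI table carries the package version
and config hashes in its header.
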