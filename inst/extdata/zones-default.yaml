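# Default zone configuration of the espath structural-code alphabet.
# Polygons are vertex lists [phi, psi] in degrees; zones follow the
# classical Ramachandran basins: a right-handed helical basin around
# (-57, -47), its inversion for the left-handed basin, a beta field in
# the upper-left quadrant containing the Psi = -Phi amyloid line, and an
# M band between the helical and beta basins. Band tolerances (degrees):
# ab_tolerance bounds the perpendicular distance to Psi = -Phi for the
# AB code; e_band splits the beta field into the rectilinear E band and
# the twisted F remainder.
version: 1
ab_tolerance: 15
e_band: 30
zone_tolerance: 15
polygons:
  R:
    - [-180, -120]
    - [-20, -120]
    - [-20, 30]
    - [-180, 30]
  L:
    - [20, -30]
    - [180, -30]
    - [180, 120]
    - [20, 120]
  beta:
    - [-180, 60]
    - [-20, 60]
    - [-20, 180]
    - [-180, 180]
  M:
    - [-180, 30]
    - [-20, 30]
    - [-20, 60]
    - [-180, 60]
  # low-energy basin cores (inversion-symmetric) used for the parabola
  # fit and path derivation; distinct from the broad classification zones
  alphaR_core:
    - [-100, -70]
    - [-40, -70]
    - [-40, -20]
    - [-100, -20]
  alphaL_core:
    - [40, 20]
    - [100, 20]
    - [100, 70]
    - [40, 70]
  beta_core:
    - [-160, 90]
    - [-60, 90]
    - [-60, 180]
    - [-160, 180]
  beta_core_inv:
    - [60, -180]
    - [160, -180]
    - [160, -90]
    - [60, -90]
low_energy: [alphaR_core, alphaL_core, beta_core, beta_core_inv]
representatives:
  AB: [-135, 135]
  R: [-57, -47]
  L: [57, 47]
  B: [-100, 135]
  E: [-120, 150]
  F: [-70, 150]
  M: [-90, 45]
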