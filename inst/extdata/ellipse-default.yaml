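# Default elliptical early-stage path, frozen from the package's own
# derivation pipeline: generate_rv_map(step = 5) -> fit_parabola (default
# low-energy mask, zones-default.yaml v1) -> derive_ellipse(tol = 0.5).
# Units: degrees in the Phi-Psi plane. Re-derive with
# es_derive_default_ellipse(); the result must reproduce these values.
version: 1
center: [-2.6506974301, -1.6688007143]
axes: [181.0429561844, 84.8429057669]
tilt: -45.8878231553
provenance: "derived: rv_map step=5, geometry_params defaults, parabola tol=0.5, zones v1"
parabola:
  c2: 1.07553728107e-04
  c1: -1.47089330706e-02
  c0: 1.24271298645
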