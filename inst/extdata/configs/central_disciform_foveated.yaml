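# As central_disciform.yaml, but the scene is first processed with the
# eccentricity-dependent contrast-sensitivity filter (foveate-then-carve),
# representing the residual blurred pericentral vision of a patient with a
# disciform macular scotoma.
display:
  width_px: 256
  height_px: 192
  span_deg: 32
scotomas:
  - shape: circle
    diameter_deg: 6
    center_deg: [0, 0]
    label: central_disciform
carve:
  direction_rule: orthogonal_to_fovea_axis
eccentricity:
  enabled: true
  K: 5
  ct0_min: 0.005
  f_peak: 4
  ecc_factor: 0.05
io:
  fixture:
    kind: random_texture
  out_dir: scotocarve_out
seed: 1
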