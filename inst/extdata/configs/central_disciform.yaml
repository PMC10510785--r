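# Central disciform scotoma demo: a 6-degree circular scotoma at fixation
# over a 32-degree scene, carved with alternating vertical/horizontal
# seams (the central rule). The input scene is a synthetic smoothed-noise
# texture generated at run time.
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
  enabled: false
io:
  fixture:
    kind: random_texture
  out_dir: scotocarve_out
seed: 1
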