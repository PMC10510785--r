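# Paracentral homonymous scotoma demo: a 5 x 8 degree ellipse centered
# 4 degrees right and 2 degrees above fixation (a lateral scotoma, so the
# fovea-axis rule selects vertical seams and the shoulder-narrowing class
# of distortions).
display:
  width_px: 300
  height_px: 200
  span_deg: 30
scotomas:
  - shape: ellipse
    width_deg: 5
    height_deg: 8
    center_deg: [4, -2]
    label: paracentral
carve:
  direction_rule: orthogonal_to_fovea_axis
io:
  fixture:
    kind: shoulder_silhouette
  out_dir: scotocarve_out
seed: 1
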