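# Early-glaucoma demo: three paracentral arcuate scotomas at 15 degrees
# mean eccentricity (thickness 3 degrees), one left, one right, one
# inferior. The exact arc geometry is a synthetic stand-in for a typical
# early arcuate field loss; each scotoma is carved separately in the
# direction orthogonal to its fovea axis.
display:
  width_px: 436
  height_px: 150
  span_deg: 109
scotomas:
  - shape: arcuate
    mean_radius_deg: 15
    angular_start_deg: 315
    angular_extent_deg: 90
    thickness_deg: 3
    label: right_arcuate
  - shape: arcuate
    mean_radius_deg: 15
    angular_start_deg: 135
    angular_extent_deg: 90
    thickness_deg: 3
    label: left_arcuate
  - shape: arcuate
    mean_radius_deg: 15
    angular_start_deg: 60
    angular_extent_deg: 60
    thickness_deg: 3
    label: inferior_arcuate
carve:
  direction_rule: orthogonal_to_fovea_axis
io:
  fixture:
    kind: random_texture
  out_dir: scotocarve_out
seed: 1
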