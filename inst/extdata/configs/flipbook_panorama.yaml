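# Flipbook demo: a synthetic 109-degree panorama scanned with ten
# 2-second fixations; at each fixation the three arcuate scotomas are
# carved relative to that fixation and the result is cropped to the
# 45-degree display span with the fixation at the center. 25 fps, no blur
# frames between fixations.
display:
  width_px: 180
  height_px: 150
  span_deg: 45
fixations:
  - [140, 75]
  - [158, 75]
  - [176, 75]
  - [194, 75]
  - [212, 75]
  - [229, 75]
  - [247, 75]
  - [265, 75]
  - [282, 75]
  - [300, 75]
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
video:
  fps: 25
  dwell_s: 2.0
io:
  fixture:
    kind: panorama
    span_deg: 109
    ppd: 4
    height_px: 150
  out_dir: scotocarve_out
seed: 1
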