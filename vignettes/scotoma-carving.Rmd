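---
title: "Scotoma carving: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scotoma carving: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scotocarve)
```

## The problem

A scotoma is a region of the visual field insensitive to stimulation.
Patients with discrete binocular scotomas — central disciform scotomas in
macular degeneration, paracentral arcuate defects in glaucoma, cortical
paracentral losses — almost never perceive a dark patch. The elided
content is simply missing, the surrounding scene appears continuous, and
what remains measurable are secondary spatial distortions: a shoulder
that looks thinner, a line through the scotoma that looks shorter, bent
door frames. `scotocarve` renders that percept by *carving*: the content
under the scotoma is removed along minimum-energy seams and never
replaced, so the flanking content closes into apposition.

This is a rendering hypothesis, not a mechanistic claim about cortical
processing; its value is that many patient-reported effects (line
shortening, shoulder thinning, invisibility of the defect, objects
disappearing into and reemerging from peripheral scotomas during
locomotion) emerge from it without further assumptions.

## The carving engine

Energy is the 3×3 Prewitt gradient magnitude on Rec.601 luminance, with
edge-replicated borders. Seams are monotone 8-connected paths with one
pixel per row (vertical) or column (horizontal); the minimum-energy seam
is found by the standard dynamic program over the three predecessors of
each pixel and removed, and the energy is recomputed before the next
extraction.

Two readings of seam selection are possible from the verbal descriptions
this method circulates under: greedy next-pixel descent, and ranking of
pre-constructed seams removed as a batch. We implement neither: greedy
construction is not guaranteed minimal, and batch removal invalidates
seam coordinates after the first deletion. The globally optimal DP with
recomputation after each removal is the canonical formulation, satisfies
every invariant the other readings imply (one pixel per row, ≤45°
deviation, width reduction of one per seam), and is what the test suite
pins down, including against exhaustive enumeration of all monotone
seams on small instances.

Tie-breaking is deterministic everywhere: predecessor offsets are
resolved in the order −1, 0, +1 and final-row minima toward the smallest
column, so identical inputs always produce identical seams.

## Forcing seams through the scotoma

During carving of a scotoma, its mask pixels receive energy
`M = −(L·(Emax + P) + 1)`, where `L` is the seam length, `Emax` the
current maximum natural energy, and `P = L·Emax + 1` the penalty
assigned to *other*, not-yet-carved scotomas. Any seam containing a mask
pixel then has total energy below any mask-avoiding seam, and any seam
entering another scotoma's mask is dearer than any natural seam — so
each optimal seam provably intersects the active mask and no other. The
loop removes seams until the active mask is empty; masks and the
coordinate map are carried through every removal as auxiliary rasters so
they stay aligned with the shrinking image. Multiple scotomas are carved
separately, by decreasing eccentricity by default.

Seam direction: a mask containing the fixation pixel is classified
central and carved with strictly alternating vertical/horizontal seams
(starting vertical); otherwise the default rule carves orthogonally to
the fovea–scotoma axis — vertical seams when the centroid's horizontal
offset dominates (ties vertical) — which pushes the distortions away
from the fovea. An elongation rule (carve along the longer mask
dimension, needing fewer seams) and fixed directions are available. No
numeric eccentricity cutoff separates "central" from "peripheral":
containment of the fixation pixel is the criterion.

The `CoordMap` records every output pixel's source coordinate in the
original frame; it stays injective, never cites a removed pixel, and
yields the displacement field (source minus embedded output coordinate)
and the distortion map (its finite-difference gradient magnitude), which
is how the "seams converge into the scotoma" effect is quantified rather
than eyeballed.

## Display geometry

Scotomas are specified in visual degrees relative to fixation and
rasterized through a display model with `ppd = width_px / span_deg`. The
mapping is linear by default: the demonstrations use moderate spans
described only approximately ("approximately 45°"), linearity keeps the
pixel size of a scotoma independent of where fixation lands, and the
companion tangent (flat-screen) mapping is available via
`mapping = "tangent"` where exactness at wide angles matters. Pixel
coordinates are 1-based with y increasing downward, so positive vertical
degree offsets are the inferior field; a pixel belongs to a mask when
its center lies inside the analytic shape boundary, which is
deterministic and converges to the analytic area as ppd grows (the test
suite requires <1% relative error for a 6° disc at 10 ppd). Mask PNGs
are taken as nonzero = scotoma and must match the image size exactly —
resampling a perimetric mask would silently change the simulated defect.

## The eccentricity filter

Contrast sensitivity declines with retinal eccentricity; a patient with
a central scotoma sees with pericentral retina and describes the result
as "blurred". The filter models detection, not blur: the image is
decomposed into `K` octave bands by cosine-log radial filters in the
frequency domain (band `k` centered at `ppd/2^(k+1)` cycles/degree; the
filters partition unity, so bands plus the residual lowpass reconstruct
the input to floating point). Per band, the local band-limited contrast
`c_k = b_k / max(l_k, ε)` (with `l_k` the lowpass content below the
band, `ε` = 1% of range guarding dark regions) is compared against

`CT(f, e) = CT0(f) · 10^(k_e · f · e)`

and subthreshold coefficients are zeroed outright — eliminated, like the
carved content, not attenuated. `CT0(f)` is a log-parabola with minimum
0.005 at 4 cpd, and the single eccentricity factor defaults to
`k_e = 0.05 deg⁻¹·cpd⁻¹`. These defaults carry the right monotone
structure (thresholds grow with `f·e`; retention falls with
eccentricity; luminance is preserved because the residual is never
touched) but are placeholders in magnitude: the psychophysically
calibrated single-factor value and CSF table from the literature the
model follows are not reproduced here, and both parameters are exposed
in `csf_params()` and the YAML config for calibration. The pipeline
order with carving is foveate-then-carve.

## Dynamics

Saccades are why carved scotomas stay invisible in life: each saccade
replaces the whole retinal image, masking the change in local
distortions. Three generators reproduce this:

* `make_flip_video()` — abrupt alternation of two carved views;
  optionally one `blur_ms` transition frame (Gaussian σ = 10 px mean of
  the two frames, or mid-gray blank) per switch, emulating saccadic
  blur/suppression. 40 ms at 25 fps is exactly one frame.
* `make_guided_gaze()` — the fixation marker jumps first, the scene
  switches `round(delay·fps)` frames later; the 200 ms default is an
  average saccadic latency, and at 25 fps the offset is exactly 5
  frames. The observer's own saccade then masks the switch.
* `make_flipbook()` — a panorama wider than the display is scanned with
  a sequence of 2 s fixations; each view is carved with the scotomas
  placed relative to that fixation and cropped to the display span
  (45°) with fixation centered. No inter-fixation blur frames are
  needed. If horizontal seams shrink the view below the crop height,
  edge-replicated rows restore it so all frames share one size.
* `carve_video()` — per-frame carving of a supplied video with a
  per-frame fixation track (the optic-flow situation: peripheral
  objects sweep into and out of the scotomas). Frames are carved
  independently — no temporal seam coherence — which can flicker where
  seams are unstable; this is documented behavior, and fixed fixation
  plus static frames yields bitwise-identical output frames.

Default fps is 25 so that the 200 ms delay and 2 s dwell are whole frame
counts; the frame-count closed forms are asserted by the tests. Videos
are emitted as directories of numbered lossless PNG frames (byte-level
determinism is part of the contract); container encoding is left to
external tools.

## Fixtures

`generate_fixture()` builds every test input deterministically from a
seed: a noise scene with an embedded 30 px line (line-shortening
measurements), an Amsler-style grid (carving mechanics only — a
perimetric chart, deliberately not a naturalistic stimulus, so no
perceptual claims attach to it), smoothed-noise textures (generic energy
maps with no degenerate zero-energy regions), a carpenter's-world grid
(architectural distortion visibility), a head-and-shoulders silhouette,
a 109° panorama with landmark bars, grating patchworks (eccentricity
filter checks), and a moving-square video (occlusion by peripheral
scotomas). Each ships ground truth (line coordinates, grid positions,
per-frame square position) so carving assertions are exact integer
comparisons. What the fixtures do *not* emulate is the statistics of
natural scenes — passing tests demonstrate the mechanics and accounting
of the method, not the perceptual invisibility reported with natural
images, which requires human observers.

## Problem sizes and numerical choices

The packaged demonstrations run at reduced resolution chosen as the
smallest sizes at which the geometry is non-degenerate: 120–256 px
scenes at 4–8 px/deg for carving suites, a 436×150 px panorama (109° at
4 ppd) for the flipbook, 128 px rasters for pyramid tests (a K-level
pyramid needs `2^(K+2)` pixels along the short side). DP cost rows are
computed vectorized; a full carve of a 6° central scotoma at 8 ppd (66
seams on a 192×256 scene) takes about 1.5 s.

Degenerate inputs are defined: empty scotoma lists are the identity;
shapes falling outside the frame rasterize to an empty mask with a
warning flag; an iteration guard errors, naming the scotoma, if a mask
cannot be emptied; 1-column cost maps are prefix sums; constant images
have zero energy and their leftmost column is the canonical seam.

## Known limitations

* Scotomas extending to the field edge (hemianopia, quadranopia, tunnel
  vision) are out of scope — carving assumes a seeing surround on the
  seam's path; a full-height strip mask degenerates to plain column
  deletion, which reproduces the vertically-split percept geometry but
  nothing subtler.
* The eccentricity filter's magnitudes are uncalibrated placeholders
  (see above).
* No seam insertion, forward energy, temporal seam coherence, or
  counter-distortion remapping; no monocular-field combination — the
  binocular scotoma is taken as given.
* Perceptual validation (invisibility to human observers) is inherently
  outside what this code can test; the suite verifies structure, exact
  accounting, and determinism.
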