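Package: scotocarve
Title: Scotoma Carving Simulation of Vision with Visual Field Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the appearance of scenes to observers with discrete
    binocular scotomas by content-aware seam carving: the image content
    elided under a scotoma is removed along minimum-energy seams forced
    through the scotoma region, closing the surrounding content into
    apposition without replacement. Includes pixel/visual-degree display
    geometry, parametric scotoma rasterization (circle, ellipse, arcuate),
    a dynamic-programming seam-carving engine with Prewitt gradient energy,
    displacement/distortion-field accounting, an eccentricity-dependent
    contrast-sensitivity (foveation) filter built on a cosine-log contrast
    pyramid, generators for saccade flip/guided-gaze videos, panorama
    flipbooks and per-frame video carving, deterministic synthetic test
    fixtures, and a YAML-configured pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
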