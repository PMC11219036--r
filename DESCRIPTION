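Package: fxmtools
Title: Single-Cell Volumetry and Motility from Fluorescence Exclusion Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Measures absolute single-cell volumes and migration statistics
    from fluorescence exclusion microscopy (FxM) time lapses of cells in
    shallow microfluidic chambers. Provides edge-based foreground
    segmentation with seeded instance splitting, frame-to-frame track
    linking, multiquadric flatfield correction, pillar-based intensity
    calibration, dye-exclusion volume integration, and track kinematics
    (windowed velocity, angular alignment). Includes a synthetic FxM
    experiment generator with per-cell ground truth for validation, plus
    buoyant-density gradient and Coulter-counter quantifications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
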