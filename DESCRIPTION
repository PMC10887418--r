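Package: nanomech
Title: AFM Force-Curve Nanomechanics for Cell and Tissue Stiffness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for atomic force microscopy (AFM) force
    spectroscopy of soft biological samples. Converts raw piezo/deflection
    ramps to force-indentation curves, locates the tip-sample contact point,
    and extracts Young's moduli with the Sneddon (pyramidal tip) and Hertz
    (spherical tip) contact models under class-specific indentation limits.
    Builds per-pixel stiffness maps from force volumes with region summaries
    and blue-to-red renderings, computes cell-shape morphometrics (area,
    perimeter, aspect ratio, circularity, solidity) and lesion/body area
    ratios from segmented images, and runs a normality-driven two-group
    comparison (Shapiro-Wilk, Levene, Student/Welch t or Wilcoxon rank-sum)
    with significance stars. Includes cantilever calibration (thermal-tune
    spring constant, contact-mode deflection sensitivity) and synthetic-data
    generators with known ground truth for force curves, force volumes,
    thermal traces, cell images and two-group samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    png,
    car,
    EBImage,
    igraph
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
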