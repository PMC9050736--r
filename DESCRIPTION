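Package: somitometry
Title: Morphometry, Volumetry and Segmentation-Clock Analysis for Somitoid Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for stem-cell-derived somitoid organoids.
    Extracts the posterior-anterior midline of a somitoid from a binary body
    mask via the Euclidean distance transform, computes the perpendicular
    width profile along a smoothing-spline midline, and calls individual
    somites from the profile extrema (inter-somite distance, width, area,
    circularity, first-somite geometry). Quantifies 3-D lineage-marker
    expression-domain volumes from multi-channel HCR stacks with anisotropic
    voxels, and analyses segmentation-clock reporter movies (kymographs,
    detrended oscillation traces, instantaneous phase, peak-to-peak period,
    posterior-anterior wave lag, somite-formation event periods). Ships a
    seeded synthetic-data generator that emits ground-truthed somitoid
    images, HCR stacks, clock movies and event series for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
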