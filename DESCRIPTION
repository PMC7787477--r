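Package: aoreg
Title: Volumetric Registration of Adaptive-Optics OCT Retinal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine three-dimensional registration of fast B-scans in
    adaptive-optics optical coherence tomography (AO-OCT) retinal volumes,
    combining phase-only correlation with overlap-normalized cross-correlation,
    cascaded with a multi-reference global solver that maps every B-scan and
    every A-line into a motion-free global coordinate system and corrects
    inter-video torsion and scale with an en-face affine stage. Includes a
    synthetic cone-mosaic phantom and fixational eye-movement simulator
    (drift, tremor, microsaccades, axial head motion, torsion, scaling) for
    parameter-recovery validation, cone-mosaic power-spectrum image-quality
    metrics (relative spectral contrast, image sharpness ratio, mean squared
    error, mosaic signal-to-noise ratio), and readers/writers for HDF5 and
    multi-page TIFF volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
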