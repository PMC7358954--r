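Package: stereonav
Title: Coordinate Navigation for Stereotactic Neurosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rigid and affine coordinate transformations between the
    anatomical (mid-commissural, AC-PC based), stereotactic frame,
    surgical head-stage, and brain-atlas coordinate systems used in
    stereotactic neurosurgery. Builds frame-to-anatomy change-of-basis
    transforms from three intracranial landmarks or from least-squares
    landmark fits, converts frame dial readings (ring, arc) into
    trajectory rotations, computes head-stage adjustments and targeting
    errors, interpolates positions along a fixed entry-target
    trajectory, and maps anatomical points onto atlas slice stacks via
    point-to-plane projection, line-plane intersection, and 3D-to-2D
    screen calibration. Includes a JSON/CSV case-file format, a
    synthetic-case generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
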