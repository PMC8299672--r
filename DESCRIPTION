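Package: orthomount
Title: Virtual Articulator Mounting and Digital Model Surgery Planning
Version: 0.1.0
Authors@R:
    person("Ortho", "Mount", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Digital counterpart of articulator-based orthognathic surgery
    planning. Computes articulator-equivalent mounting parameters (face-bow
    geometry, occlusal-plane angle, arbitrary hinge-axis position) from four
    cephalometric landmarks, assesses transverse occlusal cant from frontal
    photographs, virtually mounts intraoral-scan meshes in a y-up world frame
    with an arbitrary hinge axis, plans rigid jaw movements, measures pivot
    displacements, detects occlusal contacts, and assembles splint-fabrication
    STL export sets. Includes a deterministic synthetic-case generator that
    projects a known 3D mounting configuration to 2D landmarks, serving as
    ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
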