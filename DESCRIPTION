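Package: dentition
Title: Tooth and Jaw Biomechanics from 3D Surface Meshes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies whole dentitions from segmented 3D data. Reads
    per-tooth triangle meshes (PLY, OBJ, STL), labelled segmentation
    volumes (NRRD, NIfTI) and jaw landmarks (3D Slicer FCSV, JSON);
    detects each tooth's tip and base from its principal axis; measures
    height, width, aspect ratio and surface area; models the jaw as a
    static third-class lever to estimate per-tooth mechanical advantage,
    output force and stress; and classifies teeth as functionally
    homodont or heterodont with a bootstrap null distribution of residual
    stresses thresholded by exact one-dimensional k-medoids clustering.
    Includes a parametric cone-tooth jaw simulator with analytic ground
    truth and a command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
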