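Package: cataractgrader
Title: LOCS III Cataract Grading from Anterior-Segment Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Image preprocessing, hand-crafted feature extraction and
    shallow neural-network grading of cataract severity on the four LOCS
    III scales (nuclear opalescence, nuclear colour, cortical and
    posterior subcapsular). For slit-beam photographs the package
    suppresses specular bright spots and localizes the lens by a maximum
    inscribed white-ellipse search; for retro-illumination photographs it
    segments the pupil with a minimum enclosing circle, fills flash
    highlights by three-way colour clustering and refines localization
    with a circular Hough transform. Fuzzy-interval colour proportions,
    Hough line statistics and lesion contour statistics feed per-type
    two-layer sigmoid networks. A grade-controlled synthetic image
    generator provides reproducible fixtures and an end-to-end evaluation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
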