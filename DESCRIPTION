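Package: chemotax
Title: Automated Scoring of Quadrant Chemotaxis Assay Plate Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Turns photographs of quadrant chemotaxis-assay plates into
    chemotaxis indices (CIs). The pipeline detects the circular plate
    boundary, flattens illumination, segments nematode objects from the
    agar background, filters non-nematode objects (debris specks,
    compound spot-edge rings), measures nematode pixel area per quadrant,
    and scores each plate with the chemotaxis index, using pixel area as
    a proxy for animal counts so that tightly clumped animals do not
    produce counting errors. Includes a synthetic plate-image generator
    with exact ground truth for end-to-end verification, a command-line
    interface for batch scoring, and method-agreement statistics
    (automated-versus-manual regression, strain-effect ANOVA, and
    broad-sense heritability from variance components).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    tiff,
    png,
    withr
Config/testthat/edition: 3
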