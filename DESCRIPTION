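Package: sicklestain
Title: Quantitative Analysis of Paper-Based Sickle Cell Screening Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for developing and evaluating paper-based colorimetric
    screening tests for sickle cell anemia. Implements the S-index (the ratio
    of mean red color intensity in a blood stain's center spot to that in its
    peripheral ring), automatic stain segmentation from scanned images, blood
    sample reconstitution arithmetic, diagnostic accuracy metrics, Fleiss'
    kappa rater agreement, ROC-based limit-of-detection estimation, reagent
    shelf-life analysis, and kit cost accounting. A synthetic stain generator
    with ground-truth segmentation masks and a stochastic observer model make
    the full pipeline testable without scanned data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
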