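Package: thermoroi
Title: Illumination-Adaptive Detection and Temperature Extraction of
    Body-Surface Regions in Dairy-Cow Thermograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for extracting radiometric skin temperatures from
    regions of interest (lower udder, perianal area) on dairy-cow images
    captured together with co-registered thermal maps.  Provides a
    grayscale illumination gate that routes frames to a Retinex-based
    low-light enhancer or to contrast-limited adaptive histogram
    equalization (CLAHE) for overexposure; a text-prompt-conditioned
    miniature detection head with attention-refined, text-modulated
    feature fusion; a task-aligned label assigner with Gaussian
    soft-constrained centre sampling and a hybrid CIoU/GIoU regression
    loss; detection metrics (precision, recall, mAP50); ROI temperature
    statistics with error summaries and Spearman-based ROI selection;
    and a seeded synthetic scene generator so the full pipeline is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
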