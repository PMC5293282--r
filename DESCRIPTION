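Package: replitrack
Title: Replisome Focus Tracking and Factory-Model Statistics for Bacterial
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying replisome (DnaN-focus)
    positioning in time-lapse and snapshot fluorescence microscopy of
    bacteria.  Detects diffraction-limited foci inside segmented cell masks,
    localizes them to sub-pixel precision by Gaussian fitting, filters them
    with a significance score, fits per-cell exponential growth curves,
    classifies inter-focus separations with a two-component Gaussian mixture,
    and counts co-localized versus resolved sister replication-fork pairs.
    Includes a synthetic-data generator that simulates populations of
    exponentially growing, dividing rod-shaped cells with factory-model
    replisome dynamics and renders them through a diffraction-limited point
    spread function with shot noise, so that every stage of the analysis is
    testable against exported ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
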