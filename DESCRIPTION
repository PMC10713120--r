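Package: nmjquant
Title: Automated Quantification of Neuromuscular Junction Puncta and
    Co-Localization in Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pre- and postsynaptic fluorescent puncta in calibrated
    two-channel confocal z-stacks of zebrafish neuromuscular junctions,
    splits clustered puncta into individual termini with a deterministic
    seeded-expansion algorithm, and tabulates object-based co-localization
    (fractional overlap between channels) at eleven overlap thresholds per
    region of interest. Includes per-slice preprocessing (Gaussian blur,
    histogram expansion, Otsu thresholding, despeckling), shape-based
    classification of single versus clustered puncta (area, circularity,
    aspect ratio), a synthetic stack generator with ground truth for
    validation, and a batch pipeline with CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
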