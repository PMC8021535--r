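Package: imic
Title: Immunofluorescence Multichannel Image Cytometry of Tissue Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-cell quantification of multiplexed immunofluorescence in
    tissue sections: nuclear segmentation in the DAPI master channel with a
    biologically motivated nucleus-area gate, per-channel cell-mask growing
    from the nuclear margin, background-referenced positivity thresholds
    derived from the confidence interval of the median cell/background
    ratio, and tabulation of the eight marker-combination cell populations
    in epithelium and lamina propria. Includes a synthetic tissue-phantom
    generator with full ground truth, quality controls (isotype-control ROC
    and channel-spillover checks via single-stain runs), and the
    nonparametric comparisons used for region and group contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
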