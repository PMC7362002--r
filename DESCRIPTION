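Package: netquant
Title: Quantification of Neutrophil Extracellular Traps from Multi-Channel
    Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for scoring NETosis in three-channel epifluorescence
    micrographs of neutrophils (DAPI intact nuclei, sytox orange extracellular
    DNA, immunostained neutrophil elastase): region-of-interest background
    subtraction, per-channel binarization, percent-area-NETs scoring,
    size- and circularity-filtered discrete-cell detection, and
    viable/NETosing/necrotic classification from blue/red intensity ratios
    with green colocalization. Companion tabular analyses cover
    absorbance standard-curve release quantification, myeloperoxidase (MPO)
    normalization against PMA positive controls, and a normality- and
    replicate-gated choice between parametric and rank-based group
    comparisons. Seeded synthetic-micrograph and assay-table generators
    provide ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
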