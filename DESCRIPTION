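Package: adhesioquant
Title: Quantification of Cell-Substrate Adhesions in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying focal-adhesion-like punctae in fluorescence
    images of migrating cells. Implements intensity-threshold punctae detection
    (mean + k standard deviations within a cell mask, size-filtered in square
    microns), object-based two-channel colocalization, cell-track speed and
    time-averaged mean square displacement, chemotaxis directionality gating
    with spider-plot coordinates, adhesion assembly/disassembly kinetics via
    logistic and exponential-decay fits with t-half based lifetimes, shear-flow
    detachment percentages, cell-spreading area, rear/front polarity ratios,
    and ROUT robust outlier identification. A synthetic-data module generates
    ground-truthed images, stacks, tracks, kinetic traces and detachment counts
    so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
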