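Package: immunoplate
Title: Plate-Based Immunometabolic Profiling of Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational toolbox for 96-well immunometabolic profiling of
    macrophages and other immune cells. Turns raw plate-shaped readouts
    (absorbance and fluorescence endpoints, kinetic traces, extracellular-flux
    traces, flow-cytometry event tables, Hoechst cell counts) into metabolic
    parameters and group statistics: Griess nitrite, arginase activity,
    glucose consumption and lactate production quantification; extracellular
    flux (OCR/ECAR) phase segmentation, cell-count normalization, mito/glyco
    stress-test parameters and the ATP production-rate decomposition
    (mitoATP/glycoATP); SCENITH translation-based metabolic dependencies and
    capacities; fluorescent-probe delta-MFI with inhibitor validation;
    substrate-plate maximum color-formation rates; and paired one-/two-way
    ANOVA with Dunnett or Sidak multiplicity correction. Ships a synthetic
    plate-experiment generator with known ground truth so every stage is
    testable without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
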