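Package: immunogate
Title: Automated Gating and Enumeration for Whole-Blood Multicolor Flow
    Cytometry Immunophenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated, testable pipeline for detailed immunophenotyping of
    peripheral whole blood by 10-color flow cytometry. Provides a ground-truth
    synthetic whole-blood acquisition simulator, FCS 3.1 list-mode file input
    and output, spillover compensation and the logicle (biexponential) display
    transform, reproducible morphology quality-control gates (flow stability,
    doublet discrimination, All Cells), a generic geometric and Boolean gating
    engine, a 12-panel schema identifying 37 leukocyte and non-leukocyte
    subsets plus 27 activation-marker readouts, bead-based absolute cell
    enumeration, and replicate coefficient-of-variation robustness summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
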