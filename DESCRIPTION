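Package: flowG1
Title: Cell-Cycle Phase Deconvolution and G1 Screening from DNA-Content
    Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-scale cell-cycle screens built on DNA-content
    flow cytometry of budding yeast. Deconvolves univariate DNA-content
    histograms into G1, S and G2/M fractions with the Dean-Jett-Fox mixture
    model, reproduces density-based debris autogating, classifies deletion
    strains as High or Low G1 against a 2-standard-deviation wild-type
    reference, computes screen-wide rank correlations and Welch group
    comparisons, and estimates absolute G1 duration from birth size,
    critical size and growth rate in synchronous (elutriated) cultures
    under linear or exponential growth. A seeded synthetic-data generator
    emulates list-mode cytometry samples, multi-strain screens, elutriation
    time courses and cell-volume distributions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    EBImage,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
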