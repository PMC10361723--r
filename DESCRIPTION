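Package: kupfferflow
Title: Quantitative Analysis of Left-Right Organizer Fluid Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying cilia-driven fluid flow in the zebrafish
    left-right organizer (Kupffer's vesicle) from particle tracks: polar
    kinematics (angular velocity, tangential/radial components, sector
    summaries, directionality distributions), linear mixed-effects regression
    of angular velocity on organizer coordinates and somite stage, statistical
    models of anterior angular velocity recovery after fluid extraction, and a
    probabilistic signal-integration model of symmetry breaking with
    maximum-likelihood fitting of stage sensitivity weights. Includes a
    synthetic-data generator so the full pipeline can be exercised and
    validated without raw imaging data, plus the exact and classical tests
    used for organ situs scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
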