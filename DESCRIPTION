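Package: mrdoctwin
Title: Twin-Design Mendelian Randomization Models (DoC, MR-DoC, MR-DoC2)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariance-structure implementations of the Direction-of-Causation
    (DoC) twin model and its Mendelian-randomization extensions with polygenic
    score instruments (MR-DoC, MR-DoC2). Provides exact-data simulation (sample
    covariance equal to the model-implied population covariance to machine
    precision), phenotype measurement-error injection, multigroup normal-theory
    maximum-likelihood fitting in the variance-component parameterization,
    likelihood-ratio non-centrality parameters and chi-square power, and a
    scenario pipeline that quantifies estimation bias under unmodeled
    measurement error or unshared-environment confounding and the power to
    detect causation across factorial parameter designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
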