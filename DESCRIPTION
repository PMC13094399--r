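Package: heatrisk
Title: Climate-Vulnerability Screening of Dryland Species from Heat Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening framework for assessing species' exposure to extreme
    heat under future climate scenarios. Computes species heat envelopes
    (the range of BIO5, maximum temperature of the warmest month, across a
    range polygon) from gridded climate layers, scores the overlap of
    projected future conditions with current and historical envelopes across
    a scenario ensemble, classifies species into low/moderate/high heat-risk
    tiers with a conservative standard-error upgrade rule, maps thermal
    refugia within historical ranges, screens translocation sites against
    thermal maxima, and runs the associated trait-association statistics
    (chi-squared, Kruskal-Wallis, Dunn's post hoc). Includes a synthetic-data
    generator with analytically known ground truth so the full pipeline is
    testable without external climate downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    mgcv,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
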