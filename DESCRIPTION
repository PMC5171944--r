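Package: fluxconverge
Title: Convergence Analysis of Eddy-Covariance and Biometric Forest Carbon Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for method-comparison studies of annual forest carbon
    fluxes estimated by eddy covariance (EC) and by biometric methods (BM).
    Assembles BM carbon budgets (NEP, Reco, GPP) from component fluxes,
    models flux uncertainty from biome range, method reduction factor and
    replicate years, and tests EC-BM convergence with major-axis (model II)
    regression, normality-gated paired comparisons, inverse-uncertainty
    weighted covariate screens with heteroskedasticity handling, and
    two-way ANOVA. Includes NPP gap-filling for systematically omitted
    components (branch turnover, mycorrhizae), topographic-complexity
    indices from tower-centred elevation quadrats, and a synthetic-data
    generator with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    jsonlite,
    lmtest,
    sandwich,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
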