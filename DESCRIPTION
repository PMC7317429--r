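Package: grassSi
Title: Mixed Models, Threshold Trees, and Stoichiometric Dilution Nulls
    for Grass Leaf Silicon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for analysing grass leaf silicification
    in blocked factorial nutrient-addition x grazer-exclusion field
    experiments replicated across climatically diverse grassland sites.
    Provides a synthetic-data generator emulating the hierarchical study
    design; random-intercept linear mixed models fitted by profiled
    REML/ML with adjusted treatment means, Nakagawa-Schielzeth marginal
    and conditional R-squared, and normality / non-constant-variance
    diagnostics; AIC multimodel inference with Akaike weights; CART
    regression trees with cost-complexity pruning and the
    one-standard-error rule for soil-nutrient threshold detection; a
    permutation null model that separates genuine silicon-carbon
    trade-offs from compositional stoichiometric dilution; per-site
    silicon~carbon slopes regressed on site precipitation; and
    Kennard-Stone subset selection with NIPALS partial-least-squares
    calibration for near-infrared spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nortest,
    jsonlite,
    yaml
Suggests:
    lme4,
    rpart,
    car,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
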