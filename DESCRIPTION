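Package: pengdisp
Title: Post-Fledging Dispersal Tracking and Habitat Modelling for Juvenile Penguins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse satellite-telemetry tracks of juvenile penguins
    dispersing from their natal colonies and to model their at-sea habitat.
    Filters Argos fixes to best-per-duty-cycle daily positions and computes
    migratory parameters (tracking duration, maximum displacement from the
    colony, minimum distance covered, daily travel rates); grids environmental
    covariates on a regular lon/lat lattice with moving-window proportional-
    change gradients, standardization and a Spearman collinearity screen;
    converts daily positions to presence cells and draws masked, equal-n
    pseudo-absence sets; fits a 100-replicate balanced binomial GLM ensemble
    with backward-forward stepwise AIC selection, competing-model tables,
    Akaike weights and ROC/AUC cross-validation; and projects selected models
    into categorized habitat-probability maps. A synthetic-data module
    simulates autocorrelated environmental fields, habitat-biased correlated
    random walks and Argos-like duty-cycled observations with known ground
    truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
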