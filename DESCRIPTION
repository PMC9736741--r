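Package: forestcarbon
Title: Forest Carbon Stock Accounting, Growth Projection and Total Economic Valuation
Version: 0.1.0
Authors@R:
    person("Forest", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-pool forest carbon stock accounting with the biomass
    expansion factor (BEF) method: live tree, shrub, dead wood, litter and
    harvested wood product pools in tonnes of CO2-equivalent. Fits and ranks
    five sigmoid stand growth models (logistic, Richards, Korf, Gompertz,
    Mitscherlich) by nonlinear least squares, projects stock volume over a
    century, and evaluates forest farms with four total-economic-value (TEV)
    indicators (land, standing timber, carbon fixation, biological habitat).
    Includes a synthetic inventory and growth-series generator with
    closed-form ground truth, packaged regional default-factor tables, and a
    command-line pipeline producing reproducible CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
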