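Package: isonox
Title: Nitrogen Isotope Source Apportionment of Biogenic Soil NOx Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the biogenic soil contribution to a regional NOx
    emission inventory from ambient nitrogen stable-isotope measurements.
    Converts observed d15N-NO2 to emitted d15N-NOx via an isotopic
    fractionation correction, inverts a flux-weighted isotope mass-balance
    mixing model against an a priori emission inventory to obtain the soil
    NOx source strength, propagates source-signature uncertainty through
    the inversion both analytically (first-order Taylor expansion) and by
    Monte Carlo, and converts apportioned emissions into inventory
    revisions, per-area nitrogen fluxes, and fertilizer-nitrogen fractions.
    Includes a synthetic-campaign simulator for estimator validation
    (bias, RMSE, interval coverage) and packaged fixtures of the printed
    field-campaign tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
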