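Package: ancdim
Title: Two-Dimension Antenatal Care Analysis of Institutional Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how two dimensions of antenatal care (ANC) --
    a visits dimension that is independent of the health-care delivery
    system and a PCA-based care-intensity dimension that depends on it --
    relate to institutional delivery. Provides a synthetic generator of
    DHS-like microdata with known structural parameters, construction of
    both ANC dimensions (including Cronbach's alpha for the service-item
    scale), naive probit estimation, recursive bivariate probit estimation
    with a binary instrument and a Wald test of exogeneity, counterfactual
    average predicted probabilities, descriptive cross-tabulations, and a
    Monte Carlo driver for bias, size and coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
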