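Package: domoptics
Title: Optical Proxies of Dissolved Organic Matter Aromaticity and Carbon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating dissolved organic matter (DOM) aromaticity
    and dissolved organic carbon (DOC) from optical measurements. Computes the
    ARIX fluorescence aromaticity index (emission 520/390 nm at excitation
    320 nm) together with the classic fluorescence indices (FI, HIX, BIX,
    freshness) from excitation-emission matrices, PARIX from PARAFAC component
    scores, CDOM spectral slopes (S275-295, S380-443) by log-linear and
    nonlinear fits, and SUVA254. Ships a registry of published proxy equations
    linking ARIX and PARIX to SUVA, percent aromaticity, FT-ICR-MS aromatic
    fractions and LC-OCD fractions; the ARINT interaction model predicting DOC
    from absorbance and aromaticity, with Pan-Arctic and UV-slope competitor
    models and information-criterion comparison; a Monte Carlo sensitivity
    simulation for measurement-error propagation; and a synthetic-data
    generator with closed-form ground truth for all of the above.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
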