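Package: sedshuttle
Title: Electron-Shuttle-Linked Denitrification Analysis for Lake Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for quantifying how humic-substance electron
    shuttling relates to denitrification and nitrous oxide dynamics in lake
    sediments. Provides dissolved-gas recovery from headspace equilibria
    (Henry-law mass balance with Weiss-Price and Hamme-Emerson solubility
    fits), excess-N2/N2O and diffusive-flux estimation, 15N isotope-pairing
    partitioning of N2 production into denitrification and anammox,
    microbial-fuel-cell polarization curves and maximum power density,
    16S-normalized qPCR expression ratios with paired testing and
    Benjamini-Hochberg correction, and a survey-scale driver-regression
    workflow (Spearman screening, stepwise AIC selection, standardized
    coefficients, nonlinear association and decay fits). Seeded synthetic-data
    generators emulate the field and incubation designs so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    MASS,
    car,
    lmtest,
    minpack.lm,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
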