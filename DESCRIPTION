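Package: ftirlignin
Title: Relative Lignin Quantification from ATR-FTIR Second-Derivative Spectra
Version: 0.1.0
Authors@R:
    person("Plant", "Spectroscopy Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for estimating relative lignin content in plant
    biomass from attenuated-total-reflectance Fourier-transform infrared
    (ATR-FTIR) spectra: spectral pretreatment (ATR penetration-depth
    correction, unit vector normalization, Savitzky-Golay second-derivative
    filtering, extended multiplicative scatter correction), calibration of
    lignin-specific second-derivative peaks against binary lignin/cellulose
    mixture standards with a Pearson-correlation selection gate, and tiered
    parametric/nonparametric comparison of exposed versus control cohorts.
    Satellite stages fit the four-parameter logistic dose-response model with
    bootstrap EC50 uncertainty and compute hypergeometric Gene Ontology fold
    enrichment with Bonferroni adjustment. A synthetic-data module generates
    mixture-standard and cohort spectra, dose-response tables, and
    gene-universe draws with known ground truth so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
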