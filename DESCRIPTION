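Package: gariqc
Title: Quality-Control Analytics for Gari (Granulated Roasted Cassava Pulp)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-reduction pipeline for the laboratory quality parameters of
    gari, the fermented, granulated and roasted cassava product: sieve-stack
    granulometry (mass-fraction distributions, median and mass-weighted mean
    diameters), tapped bulk density, swelling index, thermogravimetric
    moisture, static-jacket bomb calorimetry (benzoic-acid calibration and
    gross calorific value net of spiking fuel and ignition wire), picrate
    photometric cyanide quantification, moisture-corrected titratable acidity
    as lactic acid, and a balanced two-way factorial decomposition with ANOVA
    for grain-size by moisture effects on acidity. A synthetic-data module
    generates raw instrument readings from declared ground truth so every
    stage can be exercised end-to-end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
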