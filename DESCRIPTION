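Package: dielbal
Title: Dielectric-Balanced Force-Field Modulation and Alchemical log P Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dielectric-balancing workflow used to predict
    water-to-cyclohexane partition coefficients from alchemical solvation
    free energies. Reads and writes the GROMACS-dialect topology subset
    needed to magnify AM1-BCC partial charges and inflate Lennard-Jones
    sigma parameters (the G-DB modulation), assembles solvation free
    energies from per-lambda-window dH/dlambda data by thermodynamic
    integration, converts paired free energies into log P estimates of
    log D, and evaluates predictions against experiment with SAMPL-style
    error statistics, correlations and bootstrap uncertainties. A
    synthetic-data module generates every input the pipeline consumes,
    and a dipole-fluctuation estimator of the static dielectric constant
    supports the solvent-model registry that defines dielectric balance.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
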