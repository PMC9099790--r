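Package: corrqsar
Title: QSAR Prediction of Drug Corrosion-Inhibition Efficiency with FROLS
    Term Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-activity (QSAR) modeling of the
    corrosion-inhibition efficiency (IE%) of drug molecules on steel from
    quantum-chemical and physicochemical descriptors. Computes hard-soft
    acid-base (HSAB) conceptual-DFT reactivity descriptors from frontier
    orbital energies, identifies sparse linear models by forward regression
    orthogonal least squares (FROLS) with error-reduction-ratio scoring and an
    error-to-signal stopping rule, evaluates models by fivefold
    cross-validation with MAPE/SD/MSE/RMSE metrics, ships a frozen published
    five-term predictor with IE%-based screening categories, and implements
    the electrochemical verification mathematics: impedance- and
    polarization-derived efficiencies, constant-phase-element capacitance
    conversions, and Langmuir adsorption isotherm fitting with free-energy
    classification. A seeded synthetic-data generator supports end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
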