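Package: irquant
Title: Internal-Standard ATR-FTIR Quantitation of Actives in Tablets by PLS Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mass content (%, m/m) of an active pharmaceutical
    ingredient in tablet powder of unknown excipient composition from
    attenuated-total-reflectance infrared spectra, using a solid internal
    standard. Tablet powder is mixed with a known mass of internal standard
    (paracetamol), spectra in the 1800-1300 cm-1 window are normalized at the
    analyte band near 1697.6 cm-1 and corrected by multiplicative signal
    correction, and a NIPALS PLS-1 model relates the spectra to the analyte
    mass ratio R. Predicted R values are back-calculated to content via the
    internal-standard mass balance. Includes factor-count selection
    diagnostics (RMSEC/RMSEV, correlation coefficients), ICH-style validation
    statistics (recovery, repeatability, intermediate precision), a synthetic
    ATR-FTIR spectra generator for end-to-end testing without instrument
    data, and readers for two-column CSV and JCAMP-DX spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
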