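Package: chromaqbd
Title: Analytical Quality-by-Design Toolkit for Chromatographic Method
    Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Analytical Quality-by-Design (AQbD) development of
    liquid-chromatography assays: two-level full factorial and
    Plackett-Burman designs with coded variables, response-surface models
    with full ANOVA decomposition (lack of fit, pure error, curvature),
    Derringer-Suich desirability optimization, design-space overlay and
    Method Operable Design Region (MODR) extraction, Monte Carlo process
    capability (Cpk) simulation, Plackett-Burman robustness testing, and
    ICH Q2 style validation statistics (linearity, LOD/LOQ, recovery,
    precision, two-sample method comparison, forced-degradation
    accounting).  Ships a synthetic chromatographic-response generator
    grounded in linear-solvent-strength retention theory, and worked
    reference data from the development of an HPLC assay for the three
    curcuminoids of Curcuma longa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
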