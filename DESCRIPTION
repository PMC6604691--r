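Package: immunopet
Title: Target-Engagement Analysis for Zirconium-89 Immuno-PET Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies tissue uptake of radiolabeled monoclonal antibodies
    from multi-timepoint PET data. Separates reversible and irreversible
    (internalized) uptake components by Patlak graphical analysis against a
    plasma input function, normalizes internalization-rate slopes to a
    baseline tracer-only administration, and fits a saturable dose-inhibition
    model to estimate the half-maximal (ID50) and 90% (ID90) inhibitory mass
    doses for receptor-saturating dose selection. Includes standardized
    uptake value (SUV) quantification on voxel grids (SUVmean, SUVpeak),
    immunohistochemistry H-score arithmetic, noncompartmental
    pharmacokinetics of the unlabeled drug channel, and a synthetic-study
    generator with known ground truth so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
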