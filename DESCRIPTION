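Package: perfolink
Title: Fixed-Anchor IRT Linking of Performance Outcome Batteries to a
    Patient-Reported T-Score Metric
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates multi-task performance outcome (PerfO) batteries onto an
    established patient-reported outcome (PRO) T-score metric by fixed-anchor
    graded response model (GRM) calibration, and provides the psychometric
    pipeline surrounding such a linking study: classical test theory and Mokken
    scalability diagnostics, polychoric-correlation factor analysis with a
    diagonally weighted least squares estimator, exploratory bifactor indices
    (ECV, omega-hierarchical, PUC), differential item functioning screening by
    ordinal logistic regression with Nagelkerke pseudo R-squared change,
    marginal maximum likelihood EM estimation with fixable item parameters,
    expected a posteriori scoring on the T metric, generalized S-X2 item fit,
    Lord-Wingersky summed-score crosswalk tables, and group-level agreement
    statistics (paired standardized mean differences, Bland-Altman summaries,
    ceiling and floor rates). Includes a synthetic ordinal-response generator
    with bifactor structure, differential item functioning, ceiling effects and
    missingness so the full pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
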