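Package: windwue
Title: Attribution of Grassland Water-Use Efficiency Change to Wind-Speed
    Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for attributing changes in ecosystem water-use efficiency
    (WUE, the ratio of gross primary productivity to evapotranspiration) to
    near-surface wind speed and six other climatic drivers. Implements
    principal-components regression with back-transformed original-unit
    coefficients, Monte Carlo (bootstrap) coefficient uncertainty, a
    wind/soil-moisture interaction sensitivity, ordinary-least-squares trend
    analysis with two turning-point detectors (start-year trend scan and
    continuous segmented regression), and a per-driver contribution
    decomposition (sensitivity times trend). A seeded synthetic-data module
    generates gridded drivers with known sensitivities, a triphasic
    piecewise-linear wind trajectory, realistic cross-driver correlations,
    and flux-site tables exercising the data-screening rules, so the whole
    pipeline is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
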