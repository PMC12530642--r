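Package: iohmace
Title: Intraoperative Hypotension Exposure and Cardiac-Event Threshold Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the association between intraoperative
    hypotension and 30-day major adverse cardiac events (MACE) in older
    surgical patients. Provides artifact filtering for blood-pressure time
    series, lowest mean-arterial-pressure (MAP) moving averages, three
    hypotension exposure statistics (duration, area and time-weighted
    average below a threshold), restricted-cubic-spline logistic models,
    moving-average risk curves with a quantitative convergence detector for
    harm-threshold discovery, dose-binned adjusted association models with
    age stratification, standardized-mean-difference baseline tables, and a
    seedable synthetic perioperative cohort generator so the whole pipeline
    is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
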