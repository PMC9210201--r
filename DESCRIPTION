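Package: cgmtriage
Title: Population-Scale Continuous Glucose Monitoring Metrics, Flags, and Triage Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hardware-agnostic analysis of continuous glucose monitor (CGM)
    exports at the clinic-population scale. Reads delimited CGM exports into
    canonical per-patient series, computes consensus glycemic metrics (mean
    glucose, time in range, hypoglycemia and extreme hypoglycemia percentages,
    sensor wear) over configurable review periods and day segments, evaluates
    generic threshold flags and personalized change-from-baseline flags,
    renders a per-review population triage report, and provides a longitudinal
    cohort-evaluation harness (weekly flag rates, every-week-flagged fractions,
    confusion-matrix screening summaries) together with a seeded synthetic CGM
    cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
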