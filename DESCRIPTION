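Package: dressr
Title: Double Reading/Entry, Adjudication and Reproducibility Analysis
    for Clinical Record Abstraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for double data entry of structured variables abstracted
    from clinical records: a common data model (CDM) with range and logic
    checks, de-identification with a physically separated linkage file,
    a two-reader entry engine with conflict detection, blind adjudication,
    re-entry and escalation, acceptance-sampling quality control with a
    sqrt(n+1) fourth-week rule and control-chart trend monitoring, and a
    reproducibility analyzer reporting Cohen's kappa for categorical and
    Pearson correlation for continuous variables with 95% confidence
    intervals, eligibility filtering and per-module summaries. Includes a
    synthetic-record simulator with tiered transcription-error rates so the
    whole pipeline is testable without access to real medical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    openssl,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
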