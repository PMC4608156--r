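Package: crcscreen
Title: Cost-Effectiveness Modelling of Colorectal Cancer Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort state-transition model of colorectal neoplasm
    natural history with a screening overlay (guaiac and immunologic fecal
    occult blood testing, colonoscopy), discounted half-cycle-corrected cost,
    life-year and quality-adjusted life-year accounting, incremental
    cost-effectiveness analysis with dominance and efficiency-frontier
    identification, deterministic and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and an individual-level
    microsimulation harness for internal validation and trial replication.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
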