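#!/usr/bin/env Rscript
# One-way (univariate) sensitivity analysis on the screening-related
# parameters, for the two frontier comparisons (biennial I-FOBT vs no
# screening; annual vs biennial I-FOBT), ordered tornado-style by the width
# of the resulting ICER interval.

suppressPackageStartupMessages(library(crcscreen))
dir.create("results", showWarnings = FALSE)
params <- load_parameters(fixture_parameters_path())

paths <- list(
  "compliance.c_screen" = c(0.40, 0.80),
  "compliance.c_followup" = c(0.60, 1.00),
  "tests.ifobt.specificity" = c(0.90, 0.99),
  "tests.ifobt.sens_crc" = c(0.60, 0.95),
  "tests.ifobt.sens_high_polyp" = c(0.15, 0.45),
  "natural_history.p_normal_to_low" = c(0.008, 0.03),
  "natural_history.p_high_to_crc" = c(0.02, 0.10),
  "costs.unit_cost" = c(200, 1200),
  "costs.initial_cost" = c(8000, 50000),
  "utilities.u" = c(0.5, 1.0),
  "econ.discount_rate" = c(0, 0.05)
)

for (pair in list(c("none", "ifobt_biennial"),
                  c("ifobt_biennial", "ifobt_annual"))) {
  cat(sprintf("\n== one-way ICER sensitivity: %s vs %s ($/QALY) ==\n",
              pair[2], pair[1]))
  tor <- tornado(paths, pair, "QALY", params)
  print(tor, digits = 5)
  write.csv(tor, sprintf("results/oneway_%s_vs_%s.csv", pair[2], pair[1]),
            row.names = FALSE)
}
cat("\nwrote results/oneway_*.csv (rows ordered by ICER interval width)\n")
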