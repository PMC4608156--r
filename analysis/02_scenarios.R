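#!/usr/bin/env Rscript
# Multivariate scenarios: the three published utility sets and the
# non-discounted run, each re-running all six strategies and reporting the
# optimal-strategy lambda ranges (the published optimal-range table layout).

suppressPackageStartupMessages(library(crcscreen))
dir.create("results", showWarnings = FALSE)
params <- load_parameters(fixture_parameters_path())

rows <- list()
add_scenario <- function(label, cea) {
  r <- render_optimal_ranges(cea)
  r$scenario <- label
  rows[[length(rows) + 1L]] <<- r
  cat(sprintf("%-34s frontier: %s\n", label,
              paste(cea$frontier, collapse = " -> ")))
}

add_scenario("base case (QALY)",
             dominance_analysis(run_all_strategies(params), "QALY"))
add_scenario("base case (LY)",
             dominance_analysis(run_all_strategies(params), "LY"))

p0 <- unclass(params); p0$econ$discount_rate <- 0
p0 <- validate_parameters(p0)
add_scenario("non-discounted (QALY)",
             dominance_analysis(run_all_strategies(p0), "QALY"))
add_scenario("non-discounted (LY)",
             dominance_analysis(run_all_strategies(p0), "LY"))

for (set in c("ramsey", "ness", "sharp"))
  add_scenario(sprintf("%s utility set (QALY)", set),
               scenario_utilities(set, params))

out <- do.call(rbind, rows)
write.csv(out[, c("scenario", "lambda_low", "lambda_high", "strategy")],
          "results/optimal_ranges_scenarios.csv", row.names = FALSE)
cat("\nwrote results/optimal_ranges_scenarios.csv\n")
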