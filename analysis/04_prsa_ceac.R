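#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis and cost-effectiveness acceptability
# curves.  Betas for probabilities/rates/utilities, log-normals for costs
# (method-of-moments around the fixture values); registry cancer mortality,
# time horizon and discount rate stay fixed.
#
# Usage: Rscript analysis/04_prsa_ceac.R [iterations] [seed]

suppressPackageStartupMessages(library(crcscreen))
dir.create("results", showWarnings = FALSE)
args <- commandArgs(trailingOnly = TRUE)
n <- if (length(args) >= 1) as.integer(args[1]) else 2000L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

params <- load_parameters(fixture_parameters_path())
cat(sprintf("PrSA: %d iterations, seed %d\n", n, seed))
t0 <- Sys.time()
draws <- prsa(n = n, seed = seed, params = params)
cat(sprintf("done in %.1f s\n", as.numeric(Sys.time() - t0, units = "secs")))

# per-iteration incremental outcomes vs no screening, one row per strategy
flat <- do.call(rbind, lapply(draws$strategies, function(s)
  data.frame(iteration = seq_len(draws$n), strategy = s,
             delta_cost = draws$delta[, s, "cost"],
             delta_ly = draws$delta[, s, "ly"],
             delta_qaly = draws$delta[, s, "qaly"])))
write.csv(flat, "results/prsa_draws.csv", row.names = FALSE)

for (measure in c("QALY", "LY")) {
  curve <- ceac(draws, measure = measure)
  write_ceac_csv(curve, sprintf("results/ceac_%s.csv", tolower(measure)))
  for (lam in c(7000, 50000)) {
    at <- curve[curve$lambda == lam, ]
    top <- at[order(-at$probability_optimal), ][1:2, ]
    cat(sprintf("at $%d/%s: %s optimal in %.1f%% of draws (runner-up %s, %.1f%%)\n",
                lam, measure, top$strategy[1], 100 * top$probability_optimal[1],
                top$strategy[2], 100 * top$probability_optimal[2]))
  }
}
write_manifest(run_manifest(params, seed = seed,
                            extra = list(script = "04_prsa_ceac.R", n = n)),
               "results/manifest_prsa.json")
cat("wrote results/prsa_draws.csv and results/ceac_{qaly,ly}.csv\n")
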