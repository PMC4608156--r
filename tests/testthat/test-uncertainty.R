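strategies <- default_strategies()

test_that("method-of-moments shapes recover their means and ranges", {
  sh <- beta_from_moments(0.6, 0.05)
  expect_equal(unname(sh[1] / sum(sh)), 0.6, tolerance = 1e-12)
  expect_equal(unname(sqrt(prod(sh) / (sum(sh)^2 * (sum(sh) + 1)))), 0.05,
               tolerance = 1e-10)
  ln <- lognormal_from_moments(500, 100)
  expect_equal(unname(exp(ln[1] + ln[2]^2 / 2)), 500, tolerance = 1e-10)
  m <- moments_from_range(10, 30)
  expect_equal(unname(m["mean"]), 20)
  expect_equal(unname(2 * qnorm(0.975) * m["se"]), 20, tolerance = 1e-12)
  expect_error(beta_from_moments(0.5, 0.6))
})

test_that("the default spec is lognormal for costs, beta for probabilities, fixed exclusions", {
  p <- fixture_params()
  spec <- prsa_spec(p)
  expect_true(all(spec$entries[["costs.unit_cost"]]$family == "lognormal"))
  expect_true(all(spec$entries[["compliance.c_screen"]]$family == "beta"))
  expect_false("natural_history.m_crc" %in% names(spec$entries))
  expect_false(any(grepl("discount|horizon", names(spec$entries))))
  expect_true(all(c("natural_history.m_crc", "mortality.crc_rate",
                    "econ.discount_rate", "econ.horizon_years")
                  %in% spec$excluded))
  # degenerate base values stay fixed (colonoscopy is the reference standard)
  expect_true(all(spec$entries[["tests.colonoscopy.specificity"]]$family == "fixed"))
})

test_that("PrSA draws are reproducible, in-support, and degenerate specs hit the base case", {
  p <- fixture_params()
  a <- prsa(n = 5, seed = 123, params = p)
  b <- prsa(n = 5, seed = 123, params = p)
  expect_identical(a$parameters, b$parameters)
  expect_identical(a$delta, b$delta)
  cs <- a$parameters[, "compliance.c_screen"]
  expect_true(all(cs >= 0 & cs <= 1))
  expect_true(all(a$parameters[, grepl("unit_cost", colnames(a$parameters))] > 0))

  deg <- prsa(spec = prsa_spec(p, rel_se = 0), n = 3, seed = 5, params = p)
  base <- run_all_strategies(p)
  for (nm in names(strategies)) {
    expect_equal(unname(deg$absolute[1, nm, "cost"]), base[[nm]]$cost,
                 tolerance = 1e-10)
    expect_equal(unname(deg$absolute[1, nm, "qaly"]), base[[nm]]$qaly,
                 tolerance = 1e-10)
    expect_equal(unname(colMeans(deg$delta[, nm, , drop = FALSE][, 1, ])),
                 c(cost = base[[nm]]$cost - base$none$cost,
                   ly = base[[nm]]$ly - base$none$ly,
                   qaly = base[[nm]]$qaly - base$none$qaly),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("CEAC fractions partition at every lambda and degenerate cases are indicators", {
  p <- fixture_params()
  dr <- prsa(n = 30, seed = 9, params = p)
  curve <- ceac(dr, lambda_grid = seq(0, 60000, by = 10000), measure = "QALY")
  agg <- tapply(curve$probability_optimal, curve$lambda, sum)
  expect_equal(as.vector(agg), rep(1, length(agg)), tolerance = 1e-12)
  # lambda = 0: the cost-minimiser (no screening) is optimal in every draw
  at0 <- curve[curve$lambda == 0, ]
  expect_equal(at0$probability_optimal[at0$strategy == "none"], 1)
  one <- ceac(prsa(n = 1, seed = 2, params = p),
              lambda_grid = c(0, 50000), measure = "LY")
  expect_true(all(one$probability_optimal %in% c(0, 1)))
})

test_that("one-way analysis validates bounds first and is flat for degenerate bounds", {
  p <- fixture_params()
  expect_error(one_way("compliance.c_screen", c(-0.2, 0.5),
                       c("none", "ifobt_biennial"), "QALY", p),
               "c_screen")
  base <- p$compliance$c_screen
  r <- one_way("compliance.c_screen", c(base, base),
               c("none", "ifobt_biennial"), "QALY", p)
  expect_equal(r$icer_low, r$icer_base, tolerance = 1e-12)
  expect_equal(r$icer_high, r$icer_base, tolerance = 1e-12)
})

test_that("lower I-FOBT specificity raises the annual-vs-biennial ICER", {
  p <- fixture_params()
  r <- one_way("tests.ifobt.specificity", c(0.90, 0.99),
               c("ifobt_biennial", "ifobt_annual"), "QALY", p)
  expect_gt(r$icer_low, r$icer_high)
  expect_gt(r$icer_low, r$icer_base)
})

test_that("tornado rows are ordered by ICER interval width", {
  p <- fixture_params()
  tor <- tornado(list("compliance.c_screen" = c(0.4, 0.8),
                      "costs.unit_cost" = c(300, 900),
                      "econ.discount_rate" = c(0, 0.05)),
                 c("none", "ifobt_biennial"), "QALY", p)
  expect_equal(nrow(tor), 3L)
  expect_true(all(diff(tor$width) <= 0))
})

test_that("utility-set scenarios load the published values and rerun the frontier", {
  p <- fixture_params()
  sharp <- use_utility_set(p, "sharp")
  expect_equal(unname(sharp$utilities$u["NORMAL"]), 0.94)
  expect_true(all(sharp$utilities$u[8:11] == 0.80))
  ness <- use_utility_set(p, "ness")
  expect_equal(unname(ness$utilities$u[c("DIAG_CRC_I", "DIAG_CRC_II",
                                         "DIAG_CRC_III", "DIAG_CRC_IV")]),
               c(0.74, 0.70, 0.50, 0.25))
  expect_error(use_utility_set(p, "nope"), "unknown")

  res <- scenario_utilities("ramsey", p)
  expect_s3_class(res, "cea_result")
  expect_true("No screening" %in% res$frontier)
  ones <- attr(scenario_utilities("all_ones", p), "outcomes")
  for (o in ones) expect_identical(o$qaly, o$ly)
})
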