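strategies <- default_strategies()

test_that("discounting follows the entry-anchored convention", {
  expect_equal(discount(c(3, 4, 5), 0), 12)
  expect_equal(discount(c(100, 100), 0.035), 100 + 100 / 1.035)
  # 25-year unit stream: annuity-due closed form
  expect_equal(discount(rep(1, 25), 0.035),
               (1 - 1.035^-25) / 0.035 * 1.035, tolerance = 1e-12)
  expect_error(discount(1, -0.1))
})

test_that("half-cycle correction is the trapezoid rule on boundary streams", {
  expect_equal(sum(half_cycle_correct(rep(7, 26))), 25 * 7)
  expect_equal(sum(half_cycle_correct(c(1, 0))), 0.5)
  set.seed(1)
  x <- runif(26)
  trapezoid <- sum((x[-1] + x[-26]) / 2)  # independent oracle
  expect_equal(sum(half_cycle_correct(x)), trapezoid, tolerance = 1e-12)
})

test_that("full survival yields the closed-form corrected discounted horizon", {
  p <- toy_survival_params(q = 0)
  out <- run_strategy(strategies$none, p)
  expected <- toy_survival_ly(0, 0.035)
  expect_equal(out$ly, expected, tolerance = 1e-10)
  expect_equal(out$qaly, expected, tolerance = 1e-10)
  expect_equal(out$cost, 0)
})

test_that("constant-hazard survival matches the geometric closed form", {
  for (q in c(0.02, 0.1, 0.35)) {
    p <- toy_survival_params(q = q)
    out <- run_strategy(strategies$none, p)
    expect_equal(out$ly, toy_survival_ly(q, 0.035), tolerance = 1e-10)
  }
  # and without discounting / without half-cycle correction
  p <- toy_survival_params(q = 0.1, discount = 0)
  expect_equal(run_strategy(strategies$none, p)$ly,
               toy_survival_ly(0.1, 0), tolerance = 1e-10)
  p2 <- toy_survival_params(q = 0.1, hcc = FALSE)
  expect_equal(run_strategy(strategies$none, p2)$ly,
               sum((1 - 0.1)^(0:24) / 1.035^(0:24)), tolerance = 1e-10)
})

test_that("occupancy is conserved and death occupancy never decreases", {
  for (pp in list(fixture_params(), synthesize_parameters(8, "extreme"))) {
    for (nm in c("none", "ifobt_annual", "colonoscopy_10y")) {
      out <- run_strategy(strategies[[nm]], pp)
      for (sx in c("male", "female")) {
        occ <- out$traces[[sx]]$occupancy
        mass <- apply(occ, 1, sum)
        expect_lt(max(abs(mass - 1)), 1e-10)
        dead <- apply(occ[, 12:14, , drop = FALSE], 1, sum)
        expect_true(all(diff(dead) >= -1e-14))
      }
    }
  }
})

test_that("accumulation matches a hand-computed three-cycle trace", {
  p <- unclass(fixture_params())
  p$econ$horizon_years <- 3L
  p$econ$exit_age <- 53L
  p <- validate_parameters(p)
  occ <- array(0, c(4, 14, 8))
  occ[1, 1, 1] <- 1                                   # all normal
  occ[2, 1, 1] <- 0.9; occ[2, 8, 1] <- 0.1            # 10% diagnosed stage I
  occ[3, 1, 1] <- 0.8; occ[3, 8, 1] <- 0.1; occ[3, 14, 1] <- 0.1
  occ[4, , ] <- occ[3, , ]
  trace <- structure(list(occupancy = occ, event_cost = c(50, 0, 25),
                          events = matrix(0, 3, 8), entry_age = 50L,
                          strategy = "toy", sex = "male"),
                     class = "cohort_trace")
  out <- accumulate_outcomes(trace, p)
  d <- 1.035^-(0:3)
  w <- c(0.5, 1, 1, 0.5)
  u <- p$utilities$u
  alive <- c(1, 1, 0.9, 0.9)
  qaly <- c(1, 0.9 * u[["NORMAL"]] + 0.1 * u[["DIAG_CRC_I"]],
            0.8 * u[["NORMAL"]] + 0.1 * u[["DIAG_CRC_I"]],
            0.8 * u[["NORMAL"]] + 0.1 * u[["DIAG_CRC_I"]])
  cont <- c(0, 0.1, 0.1, 0.1) * p$costs$continuing_cost[["I"]]
  expect_equal(out$ly, sum(w * alive * d), tolerance = 1e-12)
  expect_equal(out$qaly, sum(w * qaly * d), tolerance = 1e-12)
  expect_equal(out$cost, sum(c(50, 0, 25) * d[1:3]) + sum(w * cont * d),
               tolerance = 1e-12)
})

test_that("unit utilities make QALYs equal life-years bitwise", {
  p <- use_utility_set(fixture_params(), "all_ones")
  for (nm in c("none", "ifobt_biennial")) {
    out <- run_strategy(strategies[[nm]], p)
    expect_identical(out$qaly, out$ly)
  }
})

test_that("discounting can only shrink non-negative outcome streams", {
  p <- fixture_params()
  p0 <- unclass(p); p0$econ$discount_rate <- 0
  p0 <- validate_parameters(p0)
  for (nm in names(strategies)) {
    a <- run_strategy(strategies[[nm]], p)
    b <- run_strategy(strategies[[nm]], p0)
    expect_gte(b$cost, a$cost)
    expect_gte(b$ly, a$ly)
    expect_gte(b$qaly, a$qaly)
  }
})

test_that("QALYs never exceed life-years when utilities are at most one", {
  for (seed in c(6, 16)) {
    p <- synthesize_parameters(seed)
    out <- run_strategy(strategies$gfobt_annual, p)
    expect_lte(out$qaly, out$ly)
    expect_gte(out$cost, 0)
  }
})

test_that("cycle-event and occupancy exports carry the documented schema", {
  out <- run_strategy(strategies$ifobt_biennial, fixture_params())
  ev <- cycle_events(out$traces$male)
  expect_equal(nrow(ev), 25L)
  expect_true(all(c("strategy", "sex", "cycle", "age", "tests", "positives",
                    "colonoscopies", "polypectomies", "diagnoses_I",
                    "diagnoses_IV", "bleeds", "perforations",
                    "complication_deaths", "event_cost") %in% names(ev)))
  tr <- trace_occupancy(out$traces$male)
  expect_equal(nrow(tr), 26L * 14L * 8L)
  expect_equal(sum(tr$occupancy), 26, tolerance = 1e-9)
})
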