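strategies <- default_strategies()

test_that("kernel outcome distributions conserve probability mass", {
  p <- synthesize_parameters(9, difficulty = "extreme")
  tracks <- list(list(type = "none"), list(type = "low", years = 2L),
                 list(type = "low", years = 5L), list(type = "high", years = 1L))
  for (strat in strategies[c("ifobt_annual", "gfobt_biennial", "colonoscopy_10y", "none")])
    for (st in health_states()[1:11])
      for (tr in tracks)
        for (cyc in c(0L, 1L, 10L)) {
          k <- screening_round_kernel(st, tr, strat, cyc, p)
          expect_equal(sum(k$prob), 1, tolerance = 1e-12)
          expect_true(all(k$prob >= 0))
          expect_true(all(k$cost >= 0))
        }
  expect_error(screening_round_kernel("DEATH_CRC", list(type = "none"),
                                      strategies$none, 0L, p), "alive")
})

test_that("perfect specificity means no positives and only participation costs", {
  p <- unclass(fixture_params())
  p$tests$ifobt$specificity <- 1
  p <- validate_parameters(p)
  k <- screening_round_kernel("NORMAL", list(type = "none"),
                              strategies$ifobt_annual, 0L, p)
  expect_equal(sum(k$positives * k$prob), 0)
  expect_equal(sum(k$cost * k$prob),
               p$compliance$c_screen * p$costs$unit_cost[["ifobt"]])
})

test_that("a due colonoscopy round detects undiagnosed cancer at the participation rate", {
  p <- unclass(fixture_params())
  p$tests$colonoscopy$p_bleed <- 0
  p$tests$colonoscopy$p_perforation <- 0
  p <- validate_parameters(p)
  k <- screening_round_kernel("UNDIAG_CRC_II", list(type = "none"),
                              strategies$colonoscopy_10y, 0L, p)
  to_diag <- k$prob[k$next_state == "DIAG_CRC_II"]
  expect_equal(sum(to_diag), 0.60)
})

test_that("the positive-FOBT cascade moves the enumerated product of masses", {
  # hand-computed event tree: low-risk polyp, positive I-FOBT, follow-up
  # colonoscopy, polypectomy -> NORMAL on the 5-yearly surveillance track
  p <- fixture_params()
  k <- screening_round_kernel("LOW_RISK_POLYP", list(type = "none"),
                              strategies$ifobt_annual, 0L, p)
  cs <- p$tests$colonoscopy
  pd <- 1 - (1 - cs$p_bleed * cs$m_bleed) * (1 - cs$p_perforation * cs$m_perforation)
  expected <- p$compliance$c_screen * p$tests$ifobt$sens_low_polyp *
    p$compliance$c_followup * (1 - pd)
  moved <- k[k$next_state == "NORMAL" & k$next_track == "low", ]
  expect_equal(sum(moved$prob), expected, tolerance = 1e-15)
  expect_equal(moved$next_track_years, 0L)
  # non-participants and negatives stay untracked
  stay <- k[k$next_state == "LOW_RISK_POLYP", ]
  expect_equal(sum(stay$prob),
               (1 - 0.6) + 0.6 * (1 - p$tests$ifobt$sens_low_polyp) +
                 0.6 * p$tests$ifobt$sens_low_polyp * (1 - 0.8),
               tolerance = 1e-15)
})

test_that("surveillance schedules are 5-yearly for low-risk and annual for high-risk tracks", {
  expect_true(surveillance_due(list(type = "low", years = 5L)))
  expect_false(surveillance_due(list(type = "low", years = 4L)))
  expect_true(surveillance_due(list(type = "low", years = 7L)))
  expect_true(surveillance_due(list(type = "high", years = 1L)))
  expect_error(surveillance_due(list(type = "none")), "track")
  # the kernel acts on a due track even in a no-screening strategy cycle
  p <- fixture_params()
  k <- screening_round_kernel("HIGH_RISK_POLYP", list(type = "low", years = 5L),
                              strategies$none, 3L, p)
  expect_equal(sum(k$surveillance_colonoscopies * k$prob),
               p$compliance$c_followup, tolerance = 1e-12)
  # not-yet-due tracks are left alone and get no routine FOBT either
  k2 <- screening_round_kernel("HIGH_RISK_POLYP", list(type = "low", years = 2L),
                               strategies$ifobt_annual, 0L, p)
  expect_equal(nrow(k2), 1L)
  expect_equal(k2$prob, 1)
  expect_equal(k2$tests, 0)
})

test_that("null screening reproduces the no-screening trajectory exactly", {
  p0 <- unclass(fixture_params())
  p0$compliance$c_screen <- 0
  p0 <- validate_parameters(p0)
  base <- run_strategy(strategies$none, p0)
  for (nm in c("ifobt_annual", "colonoscopy_10y")) {
    out <- run_strategy(strategies[[nm]], p0)
    expect_equal(out$traces$male$occupancy, base$traces$male$occupancy,
                 tolerance = 0)
    expect_equal(out$cost, base$cost, tolerance = 0)
    expect_equal(sum(out$traces$male$events), 0)
  }
  # zero sensitivity with perfect specificity: same trajectory, tests happen
  p1 <- unclass(fixture_params())
  p1$tests$gfobt[c("sens_low_polyp", "sens_high_polyp")] <- list(0, 0)
  p1$tests$gfobt$sens_crc[] <- 0
  p1$tests$gfobt$specificity <- 1
  p1 <- validate_parameters(p1)
  base1 <- run_strategy(strategies$none, p1)
  out1 <- run_strategy(strategies$gfobt_annual, p1)
  expect_equal(out1$traces$female$occupancy, base1$traces$female$occupancy,
               tolerance = 0)
  expect_gt(sum(out1$traces$female$events[, "tests"]), 0)
})

test_that("lethal complications send every follow-up participant to complication death", {
  p <- unclass(fixture_params())
  p$tests$colonoscopy$p_perforation <- 1
  p$tests$colonoscopy$m_perforation <- 1
  p <- validate_parameters(p)
  k <- screening_round_kernel("LOW_RISK_POLYP", list(type = "none"),
                              strategies$ifobt_annual, 0L, p)
  dead <- k$prob[k$next_state == "DEATH_COMPLICATION"]
  expect_equal(sum(dead),
               p$compliance$c_screen * p$tests$ifobt$sens_low_polyp *
                 p$compliance$c_followup)
  expect_equal(sum(k$prob[k$next_state == "NORMAL"]), 0)
})

test_that("higher sensitivity never loses discounted life-years", {
  strat <- strategies$ifobt_biennial
  for (seed in c(4, 14)) {
    p <- unclass(synthesize_parameters(seed))
    p$tests$colonoscopy$p_bleed <- 0
    p$tests$colonoscopy$p_perforation <- 0
    p <- validate_parameters(p)
    base <- run_strategy(strat, p)$ly
    p2 <- unclass(p)
    p2$tests$ifobt$sens_crc[] <- pmin(p2$tests$ifobt$sens_crc + 0.1, 1)
    p2$tests$ifobt$sens_high_polyp <- min(p2$tests$ifobt$sens_high_polyp + 0.1,
                                          min(p2$tests$ifobt$sens_crc))
    p2 <- validate_parameters(p2)
    expect_gte(run_strategy(strat, p2)$ly, base - 1e-12)
  }
})

test_that("expected complication deaths stay within the per-colonoscopy bound", {
  p <- fixture_params()
  out <- run_strategy(strategies$colonoscopy_10y, p)
  ev <- out$traces$male$events
  cs <- p$tests$colonoscopy
  bound <- ev[, "colonoscopies"] *
    (cs$p_bleed * cs$m_bleed + cs$p_perforation * cs$m_perforation)
  expect_true(all(ev[, "complication_deaths"] <= bound + 1e-12))
  expect_true(all(ev >= 0))
})
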