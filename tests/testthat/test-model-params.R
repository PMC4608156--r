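test_that("the state space has 14 states in four sections with three absorbing deaths", {
  st <- health_states()
  expect_length(st, 14L)
  expect_equal(as.vector(table(state_sections())), c(3L, 4L, 4L, 3L))
  p <- fixture_params()
  M <- build_transition_matrix(p, 60, "female")
  for (d in c("DEATH_CRC", "DEATH_COMPLICATION", "DEATH_OTHER"))
    expect_equal(M[d, d], 1)
})

test_that("the fixture loads with the published compliance, discount and utility values", {
  p <- load_parameters(fixture_parameters_path())
  expect_equal(p$compliance$c_screen, 0.60)
  expect_equal(p$compliance$c_followup, 0.80)
  expect_equal(p$compliance$c_symptomatic, 1.0)
  expect_equal(p$econ$discount_rate, 0.035)
  expect_equal(p$costs$hkd_per_usd, 7.8)
  expect_equal(unname(p$utilities$u["NORMAL"]), 1.0)
  ram <- use_utility_set(p, "ramsey")
  expect_equal(unname(ram$utilities$u["DIAG_CRC_IV"]), 0.76)
})

test_that("out-of-range and missing inputs are rejected with the offending path", {
  p <- unclass(fixture_params())
  p$natural_history$p_low_to_high <- 1.2
  expect_error(validate_parameters(p), "p_low_to_high")
  p <- unclass(fixture_params())
  p$tests <- NULL
  expect_error(validate_parameters(p), "tests")
  p <- unclass(fixture_params())
  p$costs$unit_cost <- p$costs$unit_cost[-3]
  expect_error(validate_parameters(p), "unit_cost")
  p <- unclass(fixture_params())
  p$tests$colonoscopy$specificity <- 0.9
  expect_error(validate_parameters(p), "colonoscopy")
})

test_that("parameter documents round-trip through YAML value-for-value", {
  p <- fixture_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  a <- unclass(p); b <- unclass(p2)
  a$meta <- b$meta <- NULL
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the tabular CSV interface exports and re-imports parameter values", {
  p <- fixture_params()
  tab <- parameter_table(p)
  expect_true(all(c("parameter", "stratum", "value", "source_tag",
                    "distribution_family", "dist_arg1", "dist_arg2")
                  %in% names(tab)))
  tab2 <- tab
  i <- which(tab2$parameter == "compliance.c_screen")
  tab2$value[i] <- 0.8
  j <- which(tab2$parameter == "costs.initial_cost" & tab2$stratum == "III")
  tab2$value[j] <- 12345
  k <- which(tab2$parameter == "mortality.crc_rate" &
               tab2$stratum == "male_60_64")
  tab2$value[k] <- 0.001
  p2 <- apply_parameter_table(p, tab2)
  expect_equal(p2$compliance$c_screen, 0.8)
  expect_equal(unname(p2$costs$initial_cost[["III"]]), 12345)
  expect_equal(p2$mortality$crc_rate[p2$mortality$sex == "male" &
                                       p2$mortality$age_band_start == 60], 0.001)
})

test_that("synthesized parameter sets are valid, deterministic and ordered", {
  s1 <- synthesize_parameters(1)
  s1b <- synthesize_parameters(1)
  expect_equal(unclass(s1), unclass(s1b))
  expect_s3_class(s1, "crc_params")

  for (seed in 1:100) {
    s <- synthesize_parameters(seed)
    u <- s$utilities$u
    expect_true(all(diff(u[c("NORMAL", "LOW_RISK_POLYP", "HIGH_RISK_POLYP",
                             "DIAG_CRC_I", "DIAG_CRC_II", "DIAG_CRC_III",
                             "DIAG_CRC_IV")]) <= 0))
    expect_gt(s$natural_history$p_normal_to_low, s$natural_history$p_high_to_crc)
    expect_true(all(diff(s$natural_history$m_crc) >= 0))
    for (tn in c("gfobt", "ifobt")) {
      tt <- s$tests[[tn]]
      expect_gt(min(tt$sens_crc), tt$sens_high_polyp)
      expect_gt(tt$sens_high_polyp, tt$sens_low_polyp)
    }
    expect_gt(min(s$tests$ifobt$sens_crc), max(s$tests$gfobt$sens_crc))
    expect_gt(s$tests$ifobt$specificity, s$tests$gfobt$specificity)
    # every synthesized set passes the loader's validator via round-trip
    expect_silent(validate_parameters(s))
  }
})

test_that("synthesized documents survive the writer/loader round trip", {
  f <- withr::local_tempfile(fileext = ".yaml")
  s <- synthesize_parameters(11, difficulty = "extreme")
  write_parameters(s, f)
  s2 <- load_parameters(f)
  a <- unclass(s); b <- unclass(s2)
  a$meta <- b$meta <- NULL
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("documents carry an inline strategy list and an HKD input mode", {
  p <- load_parameters(fixture_parameters_path())
  st <- document_strategies(p)
  expect_length(st, 6L)
  expect_equal(vapply(st, function(s) s$test, character(1)),
               c("none", "gfobt", "gfobt", "ifobt", "ifobt", "colonoscopy"),
               ignore_attr = TRUE)
  expect_equal(st[[6]]$interval_years, 10L)
  # a document without the section falls back to the shipped comparators
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  expect_equal(vapply(document_strategies(load_parameters(f)),
                      function(s) s$name, character(1)),
               vapply(default_strategies(), function(s) s$name, character(1)),
               ignore_attr = TRUE)
  # HKD-denominated cost inputs are converted at the pegged rate
  hk <- load_parameters(fixture_parameters_path(), currency = "hkd")
  expect_equal(hk$costs$unit_cost, p$costs$unit_cost / 7.8)
  expect_equal(hk$costs$initial_cost, p$costs$initial_cost / 7.8)
})
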