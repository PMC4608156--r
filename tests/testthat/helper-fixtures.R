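# Shared fixtures and independent oracles for the test suite.

fixture_params <- function() default_parameters()

ref_outcomes_path <- function() {
  system.file("extdata", "reference-outcomes-hk2009.csv", package = "crcscreen",
              mustWork = TRUE)
}

# published per-person outcomes as strategy_outcome-shaped lists
ref_outcomes <- function() {
  ref <- utils::read.csv(ref_outcomes_path(), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(ref)), function(i)
    list(strategy = ref$strategy[i], cost = ref$cost[i],
         ly = ref$ly[i], qaly = ref$qaly[i]))
}

# parameters for a survival-only toy: no disease, constant annual
# other-cause death probability q in every age band
toy_survival_params <- function(q = 0, discount = 0.035, hcc = TRUE) {
  p <- unclass(default_parameters())
  p$natural_history$p_normal_to_low <- 0
  p$natural_history$p_low_to_high <- 0
  p$natural_history$p_high_to_crc <- 0
  p$natural_history$p_stage_progress[] <- 0
  p$natural_history$p_symptomatic[] <- 0
  p$natural_history$m_crc[] <- 0
  p$natural_history$initial_distribution[] <- c(1, 0, 0)
  p$mortality$all_cause_rate[] <- q
  p$mortality$crc_rate[] <- 0
  p$econ$discount_rate <- discount
  p$econ$half_cycle_correction <- hcc
  validate_parameters(p)
}

# closed-form discounted half-cycle-corrected life expectancy for the
# survival toy: boundary survival (1-q)^t, half weights at both ends
toy_survival_ly <- function(q, discount, horizon = 25L) {
  t <- 0:horizon
  w <- rep(1, horizon + 1L)
  w[c(1L, horizon + 1L)] <- 0.5
  sum(w * (1 - q)^t / (1 + discount)^t)
}

# brute-force efficiency frontier: a strategy is off the frontier iff some
# other strategy, or a convex combination of two others, attains at least
# its effectiveness at no greater cost (one strict)
brute_frontier <- function(cost, eff) {
  n <- length(cost)
  on_front <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (eff[j] >= eff[i] && cost[j] <= cost[i] &&
          (eff[j] > eff[i] || cost[j] < cost[i])) {
        on_front[i] <- FALSE
        break
      }
      for (k in seq_len(n)) {
        if (k == i || k == j || eff[j] == eff[k]) next
        a <- (eff[i] - eff[k]) / (eff[j] - eff[k])
        if (a < 0 || a > 1) next
        cmix <- a * cost[j] + (1 - a) * cost[k]
        if (cmix < cost[i]) { on_front[i] <- FALSE; break }
      }
      if (!on_front[i]) break
    }
  }
  which(on_front)
}

expect_rows_sum_to_one <- function(M, tol = 1e-12) {
  testthat::expect_lt(max(abs(rowSums(M) - 1)), tol)
}
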