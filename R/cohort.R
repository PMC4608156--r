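#' Discount a per-cycle value stream
#'
#' Present value at annual rate `rate` with time zero at model entry: the
#' first element is undiscounted, element `t` is divided by `(1+rate)^t`.
#'
#' @param stream Numeric vector of per-cycle (or per-boundary) values.
#' @param rate Annual discount rate (fraction, >= 0).
#' @return The present value (a single number).
#' @export
discount <- function(stream, rate) {
  stopifnot(rate >= 0)
  sum(stream / (1 + rate)^(seq_along(stream) - 1L))
}

#' Half-cycle correction of a boundary-valued stream
#'
#' Trapezoidal convention: state membership is evaluated at cycle
#' boundaries, and each cycle contributes the average of its start and end
#' values -- equivalently, the boundary stream is reweighted with half
#' weight on the first and last evaluation.  A constant stream over T
#' cycles (T+1 boundaries) therefore still totals T times the constant.
#'
#' @param stream Numeric vector of T+1 boundary evaluations.
#' @return Reweighted stream of the same length whose plain (or discounted)
#'   sum is the half-cycle-corrected total.
#' @export
half_cycle_correct <- function(stream) {
  n <- length(stream)
  stopifnot(n >= 2L)
  w <- rep(1, n)
  w[c(1L, n)] <- 0.5
  stream * w
}

.boundary_weights <- function(n_boundary, half_cycle) {
  if (half_cycle) {
    w <- rep(1, n_boundary)
    w[c(1L, n_boundary)] <- 0.5
    w
  } else {
    c(rep(1, n_boundary - 1L), 0)  # start-of-cycle counting
  }
}

# one-sex cohort recursion; occupancy is a 14x8 (state x track) matrix of
# cohort fractions, screening applied at cycle start, then the annual
# natural-history transition, then surveillance clocks advance
.run_strategy_sex <- function(strategy, params, sex, ops = NULL) {
  Tn <- params$econ$horizon_years
  TMs <- .transition_set(params, sex)
  if (is.null(ops)) ops <- .cycle_operators(strategy, params)
  uc <- params$costs$unit_cost
  sym_unit_cost <- params$costs$initial_cost +
    uc[["colonoscopy"]] + uc[["specialist_visit"]]

  occ <- matrix(0, .N_STATE, .N_TRACK)
  occ[1:3, 1L] <- params$natural_history$initial_distribution

  occupancy <- array(0, c(Tn + 1L, .N_STATE, .N_TRACK),
                     dimnames = list(NULL, .STATES, .TRACKS))
  event_cost <- numeric(Tn)
  events <- matrix(0, Tn, length(.EVENTS), dimnames = list(NULL, .EVENTS))
  new_diag <- matrix(0, Tn, 4L,
                     dimnames = list(NULL, c("I", "II", "III", "IV")))

  for (t in seq_len(Tn)) {
    occupancy[t, , ] <- occ
    age <- params$econ$entry_age + t - 1L
    op <- if (routine_round_due(strategy, age)) ops$due else ops$idle
    v <- as.vector(occ)
    event_cost[t] <- sum(v * op$cost)
    events[t, ] <- v %*% op$ev
    diag_flow <- as.vector(v %*% op$diag)
    occ <- matrix(crossprod(op$S, v), .N_STATE, .N_TRACK)

    TM <- TMs[[t]]
    sym_flow <- rowSums(occ[.S_UNDIAG, , drop = FALSE]) *
      TM[cbind(.S_UNDIAG, .S_DIAG)]
    event_cost[t] <- event_cost[t] + sum(sym_flow * sym_unit_cost)
    new_diag[t, ] <- diag_flow + sym_flow

    occ <- crossprod(TM, occ)
    dead_diag <- rowSums(occ[8:14, , drop = FALSE])
    occ[8:14, ] <- 0
    occ[8:14, 1L] <- dead_diag
    adv <- occ
    adv[1:7, 3:7] <- occ[1:7, 2:6]
    adv[1:7, 7L] <- occ[1:7, 6L] + occ[1:7, 7L]
    adv[1:7, 2L] <- 0
    occ <- adv
    if (!all(is.finite(occ)))
      stop(sprintf("non-finite occupancy at cycle %d (%s, %s)", t,
                   strategy$name, sex), call. = FALSE)
  }
  occupancy[Tn + 1L, , ] <- occ

  structure(list(strategy = strategy$name, sex = sex,
                 occupancy = occupancy, event_cost = event_cost,
                 events = events, new_diagnoses = new_diag,
                 entry_age = params$econ$entry_age),
            class = "cohort_trace")
}

#' Accumulate discounted, half-cycle-corrected outcomes from a trace
#'
#' Life-years are the alive occupancy at each cycle boundary; QALYs weight
#' the occupancy by the per-state utilities; costs combine one-off event
#' costs (tests, colonoscopies, complications, initial-phase care at
#' diagnosis), charged in full at their event cycle, with continuing-phase
#' care costs that accrue on the diagnosed stock and are half-cycle
#' corrected like the effectiveness streams.  All streams are discounted at
#' the annual rate in `params$econ`.
#'
#' @param trace A `cohort_trace` from [run_strategy()].
#' @param params The `crc_params` the trace was generated under.
#' @return List with per-person `cost`, `ly`, `qaly` (discounted).
#' @export
accumulate_outcomes <- function(trace, params) {
  occ <- trace$occupancy
  nb <- dim(occ)[1L]
  r <- params$econ$discount_rate
  d <- (1 + r)^(-(0:(nb - 1L)))
  w <- .boundary_weights(nb, isTRUE(params$econ$half_cycle_correction))

  state_mass <- apply(occ, c(1L, 2L), sum)     # boundary x state
  u <- .u_full(params)
  alive <- as.vector(state_mass[, .S_ALIVE, drop = FALSE] %*% rep(1, 11L))
  qaly <- as.vector(state_mass[, .S_ALIVE, drop = FALSE] %*% u[.S_ALIVE])
  cont <- as.vector(state_mass[, .S_DIAG, drop = FALSE] %*%
                      params$costs$continuing_cost)

  list(cost = sum(trace$event_cost * d[seq_along(trace$event_cost)]) +
         sum(w * cont * d),
       ly = sum(w * alive * d),
       qaly = sum(w * qaly * d))
}

# ---- lean outcome-only path (no trace storage), used by the PrSA loop ----

.fast_prep <- function(params) {
  surv <- .surveillance_branches(params)
  sw <- params$econ$sex_weights
  TMs <- lapply(names(sw), function(sx) .transition_set(params, sx))
  names(TMs) <- names(sw)
  Tn <- params$econ$horizon_years
  d <- (1 + params$econ$discount_rate)^(-(0:Tn))
  uc <- params$costs$unit_cost
  list(surv = surv,
       idle = .screening_operator(FALSE, "none", params, surv),
       TMs = TMs, d = d,
       wd = .boundary_weights(Tn + 1L,
                              isTRUE(params$econ$half_cycle_correction)) * d,
       u = unname(params$utilities$u),
       cont = unname(params$costs$continuing_cost),
       sym_unit = unname(params$costs$initial_cost) +
         uc[["colonoscopy"]] + uc[["specialist_visit"]])
}

.fast_outcome_sex <- function(strategy, params, sx, prep, due_op) {
  Tn <- params$econ$horizon_years
  occ <- matrix(0, .N_STATE, .N_TRACK)
  occ[1:3, 1L] <- params$natural_history$initial_distribution
  TMs <- prep$TMs[[sx]]
  wd <- prep$wd
  d <- prep$d
  ly <- qaly <- cost <- 0
  entry <- params$econ$entry_age
  for (t in seq_len(Tn)) {
    sm <- rowSums(occ)
    ly <- ly + wd[t] * sum(sm[1:11])
    qaly <- qaly + wd[t] * sum(prep$u * sm[1:11])
    cost <- cost + wd[t] * sum(prep$cont * sm[8:11])
    op <- if (routine_round_due(strategy, entry + t - 1L)) due_op else prep$idle
    v <- as.vector(occ)
    cost <- cost + d[t] * sum(v * op$cost)
    occ <- matrix(crossprod(op$S, v), .N_STATE, .N_TRACK)
    TM <- TMs[[t]]
    cost <- cost + d[t] * sum(rowSums(occ[4:7, , drop = FALSE]) *
                                TM[cbind(4:7, 8:11)] * prep$sym_unit)
    occ <- crossprod(TM, occ)
    dead <- rowSums(occ[8:14, , drop = FALSE])
    occ[8:14, ] <- 0
    occ[8:14, 1L] <- dead
    adv <- occ
    adv[1:7, 3:7] <- occ[1:7, 2:6]
    adv[1:7, 7L] <- occ[1:7, 6L] + occ[1:7, 7L]
    adv[1:7, 2L] <- 0
    occ <- adv
  }
  sm <- rowSums(occ)
  c(cost = cost + wd[Tn + 1L] * sum(prep$cont * sm[8:11]),
    ly = ly + wd[Tn + 1L] * sum(sm[1:11]),
    qaly = qaly + wd[Tn + 1L] * sum(prep$u * sm[1:11]))
}

.fast_outcome <- function(strategy, params, prep, due_op) {
  sw <- params$econ$sex_weights
  out <- c(cost = 0, ly = 0, qaly = 0)
  for (sx in names(sw))
    out <- out + sw[[sx]] * .fast_outcome_sex(strategy, params, sx, prep, due_op)
  out
}

#' Run one screening strategy through the cohort model
#'
#' Runs the deterministic cohort recursion for each sex over the full
#' horizon (annual cycles from entry age to exit age), accumulates
#' discounted half-cycle-corrected cost, life-years and QALYs per person,
#' and mixes the sexes with the configured weights.
#'
#' @param strategy A `screening_strategy`.
#' @param params A validated `crc_params` object.
#' @return A `strategy_outcome`: per-person `cost`, `ly`, `qaly`, per-sex
#'   results, and the per-sex `cohort_trace`s.
#' @export
run_strategy <- function(strategy, params) {
  ops <- .cycle_operators(strategy, params)
  sw <- params$econ$sex_weights
  traces <- lapply(names(sw), function(sx)
    .run_strategy_sex(strategy, params, sx, ops))
  names(traces) <- names(sw)
  by_sex <- lapply(traces, accumulate_outcomes, params = params)
  mix <- function(f) sum(vapply(names(sw), function(sx)
    sw[[sx]] * by_sex[[sx]][[f]], numeric(1)))
  structure(list(strategy = strategy$name, cost = mix("cost"),
                 ly = mix("ly"), qaly = mix("qaly"),
                 by_sex = by_sex, traces = traces),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s\n  cost $%.2f  LY %.4f  QALY %.4f (per person, discounted)\n",
              x$strategy, x$cost, x$ly, x$qaly))
  invisible(x)
}

#' Run all comparator strategies
#'
#' @param params A validated `crc_params` object.
#' @param strategies Named list of `screening_strategy` objects; defaults to
#'   the six shipped comparators.
#' @return Named list of `strategy_outcome`s.
#' @export
run_all_strategies <- function(params, strategies = default_strategies()) {
  lapply(strategies, run_strategy, params = params)
}

#' Per-cycle screening event summary of a trace
#'
#' @param trace A `cohort_trace`.
#' @return Data frame with one row per cycle: strategy, sex, cycle, age,
#'   expected per-person counts of tests, positives, colonoscopies,
#'   surveillance colonoscopies, polypectomies, new diagnoses by stage,
#'   bleeds, perforations, complication deaths, and screening-phase cost.
#' @export
cycle_events <- function(trace) {
  Tn <- nrow(trace$events)
  data.frame(strategy = trace$strategy, sex = trace$sex,
             cycle = seq_len(Tn) - 1L,
             age = trace$entry_age + seq_len(Tn) - 1L,
             trace$events,
             diagnoses_I = trace$new_diagnoses[, "I"],
             diagnoses_II = trace$new_diagnoses[, "II"],
             diagnoses_III = trace$new_diagnoses[, "III"],
             diagnoses_IV = trace$new_diagnoses[, "IV"],
             event_cost = trace$event_cost,
             stringsAsFactors = FALSE)
}

#' Long-format occupancy of a trace
#'
#' @param trace A `cohort_trace`.
#' @return Data frame (strategy, sex, cycle, state, track, occupancy).
#' @export
trace_occupancy <- function(trace) {
  occ <- trace$occupancy
  nb <- dim(occ)[1L]
  out <- expand.grid(cycle = 0:(nb - 1L), state = .STATES, track = .TRACKS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$occupancy <- as.vector(occ)
  out$strategy <- trace$strategy
  out$sex <- trace$sex
  out[, c("strategy", "sex", "cycle", "state", "track", "occupancy")]
}
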