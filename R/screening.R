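# Screening cascade: one cycle's screening events superimposed on the
# natural history.  The kernel enumerates, for one (state, track) pair, the
# probability-weighted outcome branches of the cascade -- participation,
# test result, follow-up colonoscopy, polypectomy and surveillance-track
# assignment, diagnosis, complications -- together with the expected costs
# and event counts each branch incurs.  The cohort engine turns the kernel
# into a linear operator over the expanded (state x track) occupancy, so
# engine and kernel cannot drift apart.

.BR_COLS <- c("next_state", "next_track", "prob", "cost",
              "tests", "positives", "colonoscopies",
              "surveillance_colonoscopies", "polypectomies",
              "bleeds", "perforations", "complication_deaths", "diag_stage")
.EVENTS <- c("tests", "positives", "colonoscopies",
             "surveillance_colonoscopies", "polypectomies",
             "bleeds", "perforations", "complication_deaths")

.branch <- function(ns, nt, prob, cost = 0, tests = 0, positives = 0,
                    colos = 0, scolos = 0, polyps = 0, bleeds = 0,
                    perfs = 0, cdeaths = 0, diag = 0) {
  c(ns, nt, prob, cost, tests, positives, colos, scolos, polyps,
    bleeds, perfs, cdeaths, diag)
}

# outcome branches of a colonoscopy reached with probability p_enter by a
# person in `state`; `from_track` marks surveillance examinations (clear
# result then continues 5-yearly surveillance instead of returning to the
# untracked population)
.colonoscopy_branches <- function(state, trackcol, p_enter, params,
                                  from_track, extra_cost = 0, tests = 0,
                                  positives = 0) {
  cs <- params$tests$colonoscopy
  uc <- params$costs$unit_cost
  pd <- 1 - (1 - cs$p_bleed * cs$m_bleed) * (1 - cs$p_perforation * cs$m_perforation)
  colo_cost <- extra_cost + uc[["colonoscopy"]] +
    cs$p_bleed * uc[["complication_bleed"]] +
    cs$p_perforation * uc[["complication_perforation"]]
  scol <- as.numeric(from_track)
  common <- list(tests = tests, positives = positives, colos = 1,
                 scolos = scol, bleeds = cs$p_bleed, perfs = cs$p_perforation)
  br <- list()
  if (pd > 0)
    br[[1L]] <- do.call(.branch, c(list(.S_DCOMP, .T_NONE, p_enter * pd,
                                        colo_cost, cdeaths = 1), common))
  p_ok <- p_enter * (1 - pd)
  out <- if (state == .S_NORMAL) {
    nt <- if (from_track) .T_LOW0 else trackcol
    do.call(.branch, c(list(.S_NORMAL, nt, p_ok, colo_cost), common))
  } else if (state == .S_LOW) {
    do.call(.branch, c(list(.S_NORMAL, .T_LOW0, p_ok,
                            colo_cost + uc[["polypectomy"]], polyps = 1), common))
  } else if (state == .S_HIGH) {
    do.call(.branch, c(list(.S_NORMAL, .T_HIGH, p_ok,
                            colo_cost + uc[["polypectomy"]], polyps = 1), common))
  } else {
    k <- state - .S_UNDIAG[1L] + 1L
    do.call(.branch, c(list(.S_DIAG[k], .T_NONE, p_ok,
                            colo_cost + params$costs$initial_cost[[k]] +
                              uc[["specialist_visit"]], diag = k), common))
  }
  br[[length(br) + 1L]] <- out
  br
}

.fobt_pos_prob <- function(state, test) {
  if (state == .S_NORMAL) 1 - test$specificity
  else if (state == .S_LOW) test$sens_low_polyp
  else if (state == .S_HIGH) test$sens_high_polyp
  else test$sens_crc[[state - .S_UNDIAG[1L] + 1L]]
}

# branch enumeration for one (state, track column) under one cycle type
.kernel_branches <- function(state, trackcol, routine_due, test, params) {
  stay <- .branch(state, trackcol, 1)
  if (!(state %in% .S_PREDIAG))
    return(matrix(stay, nrow = 1L, dimnames = list(NULL, .BR_COLS)))

  cf <- params$compliance$c_followup
  br <- NULL
  if (trackcol == .T_LOW5 || trackcol == .T_HIGH) {
    # surveillance colonoscopy supersedes routine screening this cycle;
    # non-participants keep the (capped) track clock and are due again
    br <- c(list(.branch(state, trackcol, 1 - cf)),
            .colonoscopy_branches(state, trackcol, cf, params,
                                  from_track = TRUE))
  } else if (trackcol != .T_NONE) {
    # on a surveillance track but not yet due: no routine screening
    br <- list(stay)
  } else if (routine_due && test != "none") {
    cscr <- params$compliance$c_screen
    if (test == "colonoscopy") {
      br <- c(list(.branch(state, trackcol, 1 - cscr)),
              .colonoscopy_branches(state, trackcol, cscr, params,
                                    from_track = FALSE))
    } else {
      tt <- params$tests[[test]]
      test_cost <- params$costs$unit_cost[[test]]
      ppos <- .fobt_pos_prob(state, tt)
      br <- list(
        .branch(state, trackcol, 1 - cscr),
        .branch(state, trackcol, cscr * (1 - ppos), test_cost, tests = 1),
        .branch(state, trackcol, cscr * ppos * (1 - cf), test_cost,
                tests = 1, positives = 1))
      br <- c(br, .colonoscopy_branches(state, trackcol, cscr * ppos * cf,
                                        params, from_track = FALSE,
                                        extra_cost = test_cost,
                                        tests = 1, positives = 1))
    }
  } else {
    br <- list(stay)
  }
  m <- do.call(rbind, br)
  colnames(m) <- .BR_COLS
  m[m[, "prob"] > 0, , drop = FALSE]
}

#' Screening-round outcome kernel
#'
#' Enumerates the probability-weighted outcomes of one cycle's screening
#' cascade for a person in a given health state and surveillance track:
#' non-participation, a negative test, a positive test with or without
#' follow-up colonoscopy, polypectomy with surveillance-track assignment,
#' screen detection of cancer, and fatal or non-fatal endoscopic
#' complications.  Costs and expected event counts are attached per branch.
#' A due surveillance colonoscopy supersedes the routine round; diagnosed
#' and dead states receive no screening.
#'
#' @param state Health-state name (see [health_states()]) or index; must be
#'   an alive state.
#' @param track List with `type` in `"none"/"low"/"high"` and, for tracks,
#'   `years` since the last colonoscopy.
#' @param strategy A `screening_strategy`.
#' @param cycle_index Zero-based cycle number; the attained age is
#'   `entry_age + cycle_index`.
#' @param params A validated `crc_params` object.
#' @return Data frame of outcome branches: `next_state`, `next_track`,
#'   `next_track_years`, `prob` (summing to 1), `cost`, and expected event
#'   counts (`tests`, `positives`, `colonoscopies`,
#'   `surveillance_colonoscopies`, `polypectomies`, `bleeds`,
#'   `perforations`, `complication_deaths`, `diag_stage`).
#' @export
screening_round_kernel <- function(state, track, strategy, cycle_index, params) {
  if (is.character(state)) state <- match(state, .STATES)
  if (is.na(state) || !(state %in% .S_ALIVE))
    stop("screening applies to alive states only", call. = FALSE)
  trackcol <- .track_col(track$type %||% "none", track$years %||% 0L)
  age <- params$econ$entry_age + cycle_index
  due <- routine_round_due(strategy, age)
  m <- .kernel_branches(state, trackcol, due, strategy$test, params)
  out <- as.data.frame(m)
  tr <- lapply(out$next_track, .track_of_col)
  out$next_state <- .STATES[out$next_state]
  out$next_track_years <- vapply(tr, function(t) t$years, integer(1))
  out$next_track <- vapply(tr, function(t) t$type, character(1))
  out[, c("next_state", "next_track", "next_track_years",
          setdiff(.BR_COLS, c("next_state", "next_track")))]
}

# ---- linear screening operators over the expanded occupancy --------------

.vec_idx <- function(state, trackcol) (trackcol - 1L) * .N_STATE + state

# Builds the one-cycle screening operator for a cycle type: S[i, j] is the
# probability mass moved from expanded index i to j, cost[i] the expected
# event cost and ev[i, ] the expected event counts per unit mass at i,
# diag[i, k] the expected new stage-k diagnoses.  Only untracked people in
# a routine round and people with a due surveillance colonoscopy have
# non-identity rows, so those branch sets are computed once and reused.
.screening_operator <- function(routine_due, test, params, surv = NULL) {
  n <- .N_STATE * .N_TRACK
  S <- diag(n)
  cost <- numeric(n)
  ev <- matrix(0, n, length(.EVENTS), dimnames = list(NULL, .EVENTS))
  dg <- matrix(0, n, 4L)
  if (is.null(surv)) surv <- .surveillance_branches(params)
  fill <- function(s, tc, m) {
    i <- .vec_idx(s, tc)
    S[i, ] <<- 0
    j <- .vec_idx(m[, "next_state"], m[, "next_track"])
    pr <- m[, "prob"]
    for (b in seq_along(j)) S[i, j[b]] <<- S[i, j[b]] + pr[b]
    cost[i] <<- sum(pr * m[, "cost"])
    ev[i, ] <<- pr %*% m[, .EVENTS, drop = FALSE]
    dk <- m[, "diag_stage"]
    for (b in which(dk > 0)) dg[i, dk[b]] <<- dg[i, dk[b]] + pr[b]
  }
  for (s in .S_PREDIAG) {
    fill(s, .T_LOW5, surv$low[[s]])
    fill(s, .T_HIGH, surv$high[[s]])
    if (routine_due && test != "none")
      fill(s, .T_NONE, .kernel_branches(s, .T_NONE, TRUE, test, params))
  }
  list(S = S, cost = cost, ev = ev, diag = dg)
}

.surveillance_branches <- function(params) {
  list(low = lapply(seq_len(.N_STATE), function(s)
         if (s %in% .S_PREDIAG) .kernel_branches(s, .T_LOW5, FALSE, "none", params)),
       high = lapply(seq_len(.N_STATE), function(s)
         if (s %in% .S_PREDIAG) .kernel_branches(s, .T_HIGH, FALSE, "none", params)))
}

.cycle_operators <- function(strategy, params, surv = NULL, idle = NULL) {
  if (is.null(surv)) surv <- .surveillance_branches(params)
  if (is.null(idle)) idle <- .screening_operator(FALSE, "none", params, surv)
  due <- if (strategy$test == "none") idle
  else .screening_operator(TRUE, strategy$test, params, surv)
  list(due = due, idle = idle)
}
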