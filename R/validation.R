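# Individual-level microsimulation implementing the same cycle rules as the
# cohort recursion (screening at cycle start, then the annual
# natural-history transition, then surveillance clocks advance), coded
# independently of the kernel-derived linear operators so it can serve as a
# Monte Carlo oracle for the deterministic engine.

.microsim_sex <- function(strategy, params, sex, n) {
  Tn <- params$econ$horizon_years
  r <- params$econ$discount_rate
  d <- (1 + r)^(-(0:Tn))
  wd <- .boundary_weights(Tn + 1L, isTRUE(params$econ$half_cycle_correction)) * d
  u <- .u_full(params)
  uc <- params$costs$unit_cost
  cont <- params$costs$continuing_cost
  init_cost <- params$costs$initial_cost
  cs <- params$tests$colonoscopy
  comp <- params$compliance
  TMs <- .transition_set(params, sex)
  cumTM <- lapply(TMs, function(M) t(apply(M, 1L, cumsum)))

  state <- sample(1:3, n, replace = TRUE,
                  prob = params$natural_history$initial_distribution)
  track <- rep(1L, n)           # surveillance track column
  cost <- ly <- qaly <- numeric(n)

  colonoscopy_visit <- function(idx, from_track, dt) {
    if (!length(idx)) return(invisible())
    cost[idx] <<- cost[idx] + uc[["colonoscopy"]] * dt
    bleed <- stats::runif(length(idx)) < cs$p_bleed
    perf <- stats::runif(length(idx)) < cs$p_perforation
    cost[idx] <<- cost[idx] + (bleed * uc[["complication_bleed"]] +
                                 perf * uc[["complication_perforation"]]) * dt
    die <- (bleed & stats::runif(length(idx)) < cs$m_bleed) |
      (perf & stats::runif(length(idx)) < cs$m_perforation)
    dead <- idx[die]
    state[dead] <<- .S_DCOMP
    track[dead] <<- 1L
    ok <- idx[!die]
    s <- state[ok]
    # clear examination: continue (or de-escalate to) 5-yearly surveillance
    # when reached from a surveillance track, otherwise stay untracked
    norm <- ok[s == .S_NORMAL]
    if (from_track) track[norm] <<- .T_LOW0
    lowp <- ok[s == .S_LOW]
    if (length(lowp)) {
      cost[lowp] <<- cost[lowp] + uc[["polypectomy"]] * dt
      state[lowp] <<- .S_NORMAL
      track[lowp] <<- .T_LOW0
    }
    highp <- ok[s == .S_HIGH]
    if (length(highp)) {
      cost[highp] <<- cost[highp] + uc[["polypectomy"]] * dt
      state[highp] <<- .S_NORMAL
      track[highp] <<- .T_HIGH
    }
    canc <- ok[s %in% .S_UNDIAG]
    if (length(canc)) {
      k <- state[canc] - .S_UNDIAG[1L] + 1L
      cost[canc] <<- cost[canc] + (init_cost[k] + uc[["specialist_visit"]]) * dt
      state[canc] <<- .S_DIAG[k]
      track[canc] <<- 1L
    }
    invisible()
  }

  for (t in seq_len(Tn)) {
    # boundary accounting (pre-screening)
    alive <- state <= 11L
    ly[alive] <- ly[alive] + wd[t]
    qaly[alive] <- qaly[alive] + wd[t] * u[state[alive]]
    dg <- which(state >= 8L & state <= 11L)
    cost[dg] <- cost[dg] + cont[state[dg] - 7L] * wd[t]

    age <- params$econ$entry_age + t - 1L
    dt <- d[t]

    # surveillance colonoscopies due (5-yearly low-risk clock, annual
    # high-risk clock); these supersede the routine round
    due_surv <- which(state <= 7L & (track == .T_LOW5 | track == .T_HIGH))
    if (length(due_surv)) {
      go <- due_surv[stats::runif(length(due_surv)) < comp$c_followup]
      colonoscopy_visit(go, from_track = TRUE, dt = dt)
    }

    if (routine_round_due(strategy, age)) {
      elig <- which(state <= 7L & track == 1L)
      part <- elig[stats::runif(length(elig)) < comp$c_screen]
      if (strategy$test == "colonoscopy") {
        colonoscopy_visit(part, from_track = FALSE, dt = dt)
      } else if (length(part)) {
        tt <- params$tests[[strategy$test]]
        cost[part] <- cost[part] + uc[[strategy$test]] * dt
        ppos <- c(1 - tt$specificity, tt$sens_low_polyp, tt$sens_high_polyp,
                  tt$sens_crc)
        pos <- part[stats::runif(length(part)) < ppos[state[part]]]
        fu <- pos[stats::runif(length(pos)) < comp$c_followup]
        colonoscopy_visit(fu, from_track = FALSE, dt = dt)
      }
    }

    # annual natural-history transition (snapshot: one step per person)
    cum <- cumTM[[t]]
    st0 <- state
    for (s in intersect(unique(st0), .S_ALIVE)) {
      idx <- which(st0 == s)
      nxt <- findInterval(stats::runif(length(idx)), cum[s, ]) + 1L
      if (s %in% .S_UNDIAG) {
        sympt <- idx[nxt == s + 4L]
        if (length(sympt)) {
          k <- s - .S_UNDIAG[1L] + 1L
          cost[sympt] <- cost[sympt] +
            (init_cost[k] + uc[["colonoscopy"]] + uc[["specialist_visit"]]) * dt
        }
      }
      state[idx] <- nxt
    }
    track[state >= 8L] <- 1L
    adv <- state <= 7L & track >= .T_LOW0 & track < .T_LOW5
    track[adv] <- track[adv] + 1L
  }
  alive <- state <= 11L
  ly[alive] <- ly[alive] + wd[Tn + 1L]
  qaly[alive] <- qaly[alive] + wd[Tn + 1L] * u[state[alive]]
  dg <- which(state >= 8L & state <= 11L)
  cost[dg] <- cost[dg] + cont[state[dg] - 7L] * wd[Tn + 1L]

  list(cost = cost, ly = ly, qaly = qaly, final_state = state)
}

#' Individual-level microsimulation of one strategy
#'
#' Simulates independent life histories under the same cycle rules as the
#' cohort recursion and returns mean per-person discounted cost, life-years
#' and QALYs with Monte Carlo standard errors.  Individuals are allocated
#' to sex by the configured weights.  Serves as the stochastic oracle the
#' deterministic cohort engine is validated against.
#'
#' @param strategy A `screening_strategy`.
#' @param params A validated `crc_params`.
#' @param n_individuals Number of simulated life histories.
#' @param seed Integer seed (reproducible).
#' @return A `microsim_outcome`: `cost`, `ly`, `qaly` (means), `se`
#'   (standard errors), `n`, and per-sex sample sizes.
#' @export
microsimulate <- function(strategy, params, n_individuals = 10000L, seed = 1L) {
  stopifnot(n_individuals >= 1L)
  set.seed(as.integer(seed))
  sw <- params$econ$sex_weights
  n1 <- round(n_individuals * sw[[1L]])
  ns <- stats::setNames(c(n1, n_individuals - n1), names(sw))
  samp <- list(cost = numeric(0), ly = numeric(0), qaly = numeric(0))
  for (sx in names(ns)) {
    if (ns[[sx]] == 0L) next
    res <- .microsim_sex(strategy, params, sx, ns[[sx]])
    samp$cost <- c(samp$cost, res$cost)
    samp$ly <- c(samp$ly, res$ly)
    samp$qaly <- c(samp$qaly, res$qaly)
  }
  n <- length(samp$cost)
  se <- vapply(samp, function(x) stats::sd(x) / sqrt(n), numeric(1))
  structure(list(strategy = strategy$name,
                 cost = mean(samp$cost), ly = mean(samp$ly),
                 qaly = mean(samp$qaly), se = se, n = n, n_by_sex = ns),
            class = "microsim_outcome")
}

#' @export
print.microsim_outcome <- function(x, ...) {
  cat(sprintf("<microsim_outcome> %s (n = %d)\n", x$strategy, x$n))
  cat(sprintf("  cost $%.2f (se %.2f)  LY %.4f (se %.4f)  QALY %.4f (se %.4f)\n",
              x$cost, x$se[["cost"]], x$ly, x$se[["ly"]],
              x$qaly, x$se[["qaly"]]))
  invisible(x)
}

#' Trial-replication configuration
#'
#' Describes a published screening trial to replicate: the strategy under
#' test, follow-up length, cohort size, and optional compliance overrides
#' applied to both arms.  `published_reduction` is a documentation slot for
#' the externally reported mortality reduction (fraction) the model result
#' is to be compared with; shipped values are placeholders a user should
#' replace with the published figures.
#'
#' @param name Trial label.
#' @param strategy A `screening_strategy` for the screening arm.
#' @param followup_years Follow-up window (<= model horizon).
#' @param cohort_size Persons entering each arm.
#' @param compliance Named list of compliance overrides (e.g.
#'   `list(c_screen = 0.67)`).
#' @param published_reduction Optional externally reported reduction.
#' @return A `trial_config`.
#' @export
trial_config <- function(name, strategy, followup_years, cohort_size = 100000L,
                         compliance = list(), published_reduction = NA_real_) {
  structure(list(name = name, strategy = strategy,
                 followup_years = as.integer(followup_years),
                 cohort_size = as.integer(cohort_size),
                 compliance = compliance,
                 published_reduction = published_reduction),
            class = "trial_config")
}

#' Shipped guaiac-FOBT trial replication configs
#'
#' Biennial and annual guaiac-FOBT population trials (Funen, Nottingham,
#' Minnesota).  The `published_reduction` slots are placeholder values for
#' the trial-reported colorectal-cancer mortality reductions; replace them
#' with the published figures when comparing.
#'
#' @return Named list of `trial_config`s.
#' @export
trial_configs <- function() {
  list(
    funen = trial_config("Funen (biennial G-FOBT)",
                         screening_strategy("Biennial G-FOBT", "gfobt", 2L),
                         followup_years = 17L,
                         published_reduction = 0.18),
    nottingham = trial_config("Nottingham (biennial G-FOBT)",
                              screening_strategy("Biennial G-FOBT", "gfobt", 2L),
                              followup_years = 12L,
                              published_reduction = 0.15),
    minnesota = trial_config("Minnesota (annual G-FOBT)",
                             screening_strategy("Annual G-FOBT", "gfobt", 1L),
                             followup_years = 18L,
                             published_reduction = 0.33)
  )
}

#' Colorectal-cancer mortality-rate reduction of screening vs control
#'
#' Runs the screening arm and a no-screening control arm through the cohort
#' engine under the trial configuration, accumulates cancer deaths and
#' person-years over the follow-up window (person-years cycle-wise with the
#' same half-cycle convention as the life-year outcome), and returns the
#' mortality rate per arm, the rate ratio, and the percent reduction
#' 1 - ratio.
#'
#' @param config A `trial_config`.
#' @param params A validated `crc_params`.
#' @return A `mortality_reduction` result: per-arm data frame (arm,
#'   person_years, crc_deaths, rate), `rate_ratio`, `reduction`, and an
#'   `undefined` flag when the control arm has no cancer deaths.
#' @export
mortality_reduction <- function(config, params) {
  stopifnot(inherits(config, "trial_config"),
            config$followup_years <= params$econ$horizon_years,
            config$cohort_size >= 1L)
  p <- unclass(params)
  for (k in names(config$compliance)) p$compliance[[k]] <- config$compliance[[k]]
  p <- validate_parameters(p)

  arm <- function(strategy) {
    out <- run_strategy(strategy, p)
    f <- config$followup_years
    sw <- p$econ$sex_weights
    deaths <- py <- 0
    for (sx in names(sw)) {
      occ <- out$traces[[sx]]$occupancy
      sm <- apply(occ[seq_len(f + 1L), , , drop = FALSE], c(1L, 2L), sum)
      alive <- rowSums(sm[, .S_ALIVE, drop = FALSE])
      w <- .boundary_weights(f + 1L, TRUE)
      py <- py + sw[[sx]] * sum(w * alive)
      deaths <- deaths + sw[[sx]] * unname(sm[f + 1L, .S_DCRC])
    }
    c(person_years = py * config$cohort_size,
      crc_deaths = deaths * config$cohort_size)
  }
  scr <- arm(config$strategy)
  ctl <- arm(screening_strategy("No screening", "none"))
  rates <- c(screening = scr[["crc_deaths"]] / scr[["person_years"]],
             control = ctl[["crc_deaths"]] / ctl[["person_years"]])
  undefined <- ctl[["crc_deaths"]] == 0
  ratio <- if (undefined) NA_real_ else rates[["screening"]] / rates[["control"]]
  structure(list(
    trial = config$name,
    arms = data.frame(arm = c("screening", "control"),
                      person_years = c(scr[["person_years"]], ctl[["person_years"]]),
                      crc_deaths = c(scr[["crc_deaths"]], ctl[["crc_deaths"]]),
                      rate = unname(rates), stringsAsFactors = FALSE),
    rate_ratio = ratio, reduction = if (undefined) NA_real_ else 1 - ratio,
    undefined = undefined,
    published_reduction = config$published_reduction),
    class = "mortality_reduction")
}

#' @export
print.mortality_reduction <- function(x, ...) {
  cat(sprintf("<mortality_reduction> %s\n", x$trial))
  print(x$arms, digits = 6)
  if (x$undefined) cat("  rate ratio undefined (no cancer deaths in control arm)\n")
  else cat(sprintf("  rate ratio %.4f, reduction %.1f%%\n",
                   x$rate_ratio, 100 * x$reduction))
  invisible(x)
}
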