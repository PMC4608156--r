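# Deterministic and probabilistic sensitivity analysis.

#' Beta / log-normal shapes from a mean and standard error
#'
#' Method-of-moments parameterisation used by the PrSA machinery: beta for
#' probabilities, rates and utilities; log-normal for costs.  When only a
#' plausible range is known, [moments_from_range()] treats it as a 95 %
#' central interval.
#'
#' @param mean,se Mean and standard error on the natural scale.
#' @return Named vector of the two distribution arguments.
#' @export
beta_from_moments <- function(mean, se) {
  stopifnot(mean > 0, mean < 1, se > 0, se^2 < mean * (1 - mean))
  nu <- mean * (1 - mean) / se^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' @rdname beta_from_moments
#' @export
lognormal_from_moments <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  sdlog2 <- log(1 + (se / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' @rdname beta_from_moments
#' @param min,max Bounds of a 95 % central interval.
#' @export
moments_from_range <- function(min, max) {
  c(mean = (min + max) / 2, se = (max - min) / (2 * stats::qnorm(0.975)))
}

# standard error for a probability-type mean: proportional, capped so the
# beta method-of-moments stays valid near the boundaries
.prob_se <- function(m, rel) pmin(rel * m, 0.3 * sqrt(m * (1 - m)))

#' Default PrSA distribution specification
#'
#' Assigns a sampling distribution to every parameter except the exclusions:
#' cost parameters are log-normal, probability/rate/utility parameters are
#' beta (method-of-moments around the base value with a proportional
#' standard error), and the time horizon, discount rate and registry cancer
#' mortality stay fixed.  Degenerate parameters (base value 0 or 1) and the
#' compositional entry distributions are also held fixed.
#'
#' @param params A validated `crc_params` object.
#' @param rel_se Proportional standard error applied to drawable
#'   parameters (default 0.15).
#' @return A `prsa_spec`: list of entries `(path, family, arg1, arg2,
#'   base)` plus the exclusion list.
#' @export
prsa_spec <- function(params, rel_se = 0.15) {
  p <- unclass(params)
  entries <- list()
  add <- function(path, base, family) {
    base <- stats::setNames(as.numeric(base), names(base))
    if (rel_se <= 0) family <- "fixed"  # degenerate spec: everything fixed
    a1 <- a2 <- rep(NA_real_, length(base))
    fam <- rep(family, length(base))
    for (i in seq_along(base)) {
      if (family == "beta") {
        if (base[i] <= 0 || base[i] >= 1) { fam[i] <- "fixed"; next }
        sh <- beta_from_moments(base[i], .prob_se(base[i], rel_se))
        a1[i] <- sh[1L]; a2[i] <- sh[2L]
      } else if (family == "lognormal") {
        if (base[i] <= 0) { fam[i] <- "fixed"; next }
        sh <- lognormal_from_moments(base[i], rel_se * base[i])
        a1[i] <- sh[1L]; a2[i] <- sh[2L]
      }
    }
    entries[[path]] <<- list(path = path, family = fam, arg1 = a1, arg2 = a2,
                             base = base)
  }
  nh <- p$natural_history
  add("natural_history.p_normal_to_low", nh$p_normal_to_low, "beta")
  add("natural_history.p_low_to_high", nh$p_low_to_high, "beta")
  add("natural_history.p_high_to_crc", nh$p_high_to_crc, "beta")
  add("natural_history.p_stage_progress", nh$p_stage_progress, "beta")
  add("natural_history.p_symptomatic", nh$p_symptomatic, "beta")
  add("mortality.all_cause_rate", p$mortality$all_cause_rate, "beta")
  for (tn in names(p$tests)) {
    tt <- p$tests[[tn]]
    add(paste0("tests.", tn, ".sens_low_polyp"), tt$sens_low_polyp, "beta")
    add(paste0("tests.", tn, ".sens_high_polyp"), tt$sens_high_polyp, "beta")
    add(paste0("tests.", tn, ".sens_crc"), tt$sens_crc, "beta")
    add(paste0("tests.", tn, ".specificity"), tt$specificity, "beta")
    add(paste0("tests.", tn, ".p_bleed"), tt$p_bleed, "beta")
    add(paste0("tests.", tn, ".p_perforation"), tt$p_perforation, "beta")
    add(paste0("tests.", tn, ".m_bleed"), tt$m_bleed, "beta")
    add(paste0("tests.", tn, ".m_perforation"), tt$m_perforation, "beta")
  }
  add("compliance.c_screen", p$compliance$c_screen, "beta")
  add("compliance.c_followup", p$compliance$c_followup, "beta")
  add("compliance.c_symptomatic", p$compliance$c_symptomatic, "beta")
  add("costs.unit_cost", p$costs$unit_cost, "lognormal")
  add("costs.initial_cost", p$costs$initial_cost, "lognormal")
  add("costs.continuing_cost", p$costs$continuing_cost, "lognormal")
  add("utilities.u", p$utilities$u, "beta")
  structure(list(entries = entries,
                 excluded = c("natural_history.m_crc", "mortality.crc_rate",
                              "econ.discount_rate", "econ.horizon_years",
                              "natural_history.initial_distribution",
                              "natural_history.crc_entry_stage_dist")),
            class = "prsa_spec")
}

.draw_from_entry <- function(e) {
  out <- e$base
  for (i in seq_along(out)) {
    out[i] <- switch(e$family[i],
                     fixed = e$base[i],
                     beta = stats::rbeta(1L, e$arg1[i], e$arg2[i]),
                     lognormal = stats::rlnorm(1L, e$arg1[i], e$arg2[i]),
                     stop("unknown family: ", e$family[i]))
  }
  out
}

.apply_draw <- function(params, path, value) {
  if (path == "mortality.all_cause_rate") {
    params$mortality$all_cause_rate <- pmin(value, 1)
    # keep other-cause mortality non-negative under independent draws
    params$mortality$all_cause_rate <-
      pmax(params$mortality$all_cause_rate, params$mortality$crc_rate)
    return(params)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  old <- params[[parts]]
  if (!is.null(names(old))) names(value) <- names(old)
  params[[parts]] <- value
  params
}

#' Probabilistic sensitivity analysis
#'
#' Draws every included parameter from its assigned distribution,
#' re-runs all strategies per iteration, and records the incremental cost,
#' life-years and QALYs of each strategy against no screening.
#'
#' @param spec A `prsa_spec` (default built from `params`).
#' @param n Number of Monte Carlo iterations.
#' @param seed Integer seed; identical seeds reproduce the draw matrix
#'   bitwise.
#' @param params Base `crc_params`.
#' @param strategies Named list of strategies; must contain the
#'   no-screening comparator named `"none"`.
#' @return A `prsa_draws` object: `parameters` (iteration-by-parameter draw
#'   matrix), `delta` (array iteration x strategy x c(cost, ly, qaly),
#'   vs no screening), `absolute` (same for absolute values), `seed`, `n`.
#' @export
prsa <- function(spec = NULL, n = 1000L, seed = 1L, params, strategies = default_strategies()) {
  stopifnot(n >= 1L, "none" %in% names(strategies))
  if (is.null(spec)) spec <- prsa_spec(params)
  set.seed(as.integer(seed))
  p0 <- unclass(params)
  strat_names <- names(strategies)
  npar <- sum(vapply(spec$entries, function(e) length(e$base), integer(1)))
  par_names <- unlist(lapply(spec$entries, function(e) {
    nm <- names(e$base) %||% (if (length(e$base) > 1L) seq_along(e$base) else "")
    ifelse(nzchar(nm), paste(e$path, nm, sep = "."), e$path)
  }), use.names = FALSE)
  draws <- matrix(NA_real_, n, npar, dimnames = list(NULL, par_names))
  delta <- array(NA_real_, c(n, length(strat_names), 3L),
                 dimnames = list(NULL, strat_names, c("cost", "ly", "qaly")))
  absolute <- delta

  for (it in seq_len(n)) {
    pi <- p0
    col <- 1L
    for (e in spec$entries) {
      v <- .draw_from_entry(e)
      draws[it, col:(col + length(v) - 1L)] <- v
      col <- col + length(v)
      pi <- .apply_draw(pi, e$path, v)
    }
    pi <- structure(pi, class = "crc_params")
    prep <- .fast_prep(pi)
    due_ops <- list()
    for (s in strat_names) {
      test <- strategies[[s]]$test
      if (test == "none") due <- prep$idle
      else {
        if (is.null(due_ops[[test]]))
          due_ops[[test]] <- .screening_operator(TRUE, test, pi, prep$surv)
        due <- due_ops[[test]]
      }
      absolute[it, s, ] <- .fast_outcome(strategies[[s]], pi, prep, due)
    }
    delta[it, , ] <- sweep(absolute[it, , , drop = TRUE], 2L,
                           absolute[it, "none", ])
  }
  structure(list(parameters = draws, delta = delta, absolute = absolute,
                 seed = as.integer(seed), n = as.integer(n),
                 strategies = strat_names),
            class = "prsa_draws")
}

#' Cost-effectiveness acceptability curves
#'
#' For each ceiling ratio λ on the grid and each Monte Carlo iteration, the
#' optimal strategy is the one maximising net monetary benefit
#' λ·ΔE − ΔC against no screening (no screening itself sits at 0); the
#' curve reports, per strategy, the fraction of iterations in which it is
#' optimal.  Fractions sum to one at every λ.
#'
#' @param draws A `prsa_draws` object.
#' @param lambda_grid Ceiling-ratio grid in dollars per unit effectiveness
#'   (default 0 to 100,000 by 500).
#' @param measure `"LY"` or `"QALY"`.
#' @return A `ceac_curve`: data frame (measure, lambda, strategy,
#'   probability_optimal).
#' @export
ceac <- function(draws, lambda_grid = seq(0, 100000, by = 500),
                 measure = c("QALY", "LY")) {
  measure <- match.arg(measure)
  f <- if (measure == "QALY") "qaly" else "ly"
  dc <- draws$delta[, , "cost", drop = FALSE][, , 1L]
  de <- draws$delta[, , f, drop = FALSE][, , 1L]
  if (is.null(dim(dc))) { dc <- matrix(dc, nrow = draws$n); de <- matrix(de, nrow = draws$n) }
  strat <- draws$strategies
  out <- vector("list", length(lambda_grid))
  for (g in seq_along(lambda_grid)) {
    nmb <- lambda_grid[g] * de - dc
    best <- max.col(nmb, ties.method = "first")
    frac <- tabulate(best, nbins = length(strat)) / nrow(nmb)
    out[[g]] <- data.frame(measure = measure, lambda = lambda_grid[g],
                           strategy = strat, probability_optimal = frac,
                           stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("ceac_curve", "data.frame"))
}

#' One-way (univariate) sensitivity analysis
#'
#' Re-runs the full pipeline with one parameter set to each of its bounds,
#' all else fixed, and reports the ICER of a strategy pair at the low and
#' high input alongside the base case.  Bounds are validated before any
#' model run.
#'
#' @param param_path Dotted path of the parameter (e.g.
#'   `"compliance.c_screen"` or `"tests.ifobt.specificity"`).
#' @param bounds Numeric `c(low, high)` (for vector-valued leaves, the
#'   bound is applied to every element).
#' @param pair Character pair of strategy names (less effective first) from
#'   `strategies`.
#' @param measure `"LY"` or `"QALY"`.
#' @param params Base `crc_params`.
#' @param strategies Named strategy list.
#' @return A `one_way_result`: parameter path, bounds, ICERs at low, base,
#'   high.
#' @export
one_way <- function(param_path, bounds, pair, measure = c("QALY", "LY"),
                    params, strategies = default_strategies()) {
  measure <- match.arg(measure)
  stopifnot(length(bounds) == 2L, all(pair %in% names(strategies)))
  base_val <- param_get(params, param_path)
  runs <- lapply(c(bounds[1L], NA, bounds[2L]), function(b) {
    pp <- if (is.na(b)) params else {
      v <- base_val; v[] <- b
      validate_parameters(.apply_draw(unclass(params), param_path, v))
    }
    a <- run_strategy(strategies[[pair[1L]]], pp)
    b2 <- run_strategy(strategies[[pair[2L]]], pp)
    icer(a, b2, measure)
  })
  structure(list(param_path = param_path, bounds = bounds, pair = pair,
                 measure = measure,
                 icer_low = runs[[1L]]$icer, icer_base = runs[[2L]]$icer,
                 icer_high = runs[[3L]]$icer,
                 flags = vapply(runs, function(r) r$flag, character(1))),
            class = "one_way_result")
}

#' Tornado table of one-way results
#'
#' Runs [one_way()] for several parameter paths and orders the rows by the
#' width of the resulting ICER interval, descending.
#'
#' @param paths Named list mapping parameter paths to `c(low, high)` bounds.
#' @inheritParams one_way
#' @return Data frame (parameter, low, high, icer_low, icer_base,
#'   icer_high, width), widest first.
#' @export
tornado <- function(paths, pair, measure = c("QALY", "LY"), params,
                    strategies = default_strategies()) {
  measure <- match.arg(measure)
  rows <- lapply(names(paths), function(pp) {
    r <- one_way(pp, paths[[pp]], pair, measure, params, strategies)
    data.frame(parameter = pp, low = paths[[pp]][1L], high = paths[[pp]][2L],
               icer_low = r$icer_low, icer_base = r$icer_base,
               icer_high = r$icer_high,
               width = abs(r$icer_high - r$icer_low),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$width), , drop = FALSE]
}

#' Utility-set scenario analysis
#'
#' Swaps in a named utility set (see [use_utility_set()]), re-runs every
#' strategy, and returns the dominance analysis under the chosen measure.
#'
#' @param set_name `"ramsey"`, `"ness"`, `"sharp"` or `"all_ones"`.
#' @param params Base `crc_params`.
#' @param strategies Named strategy list.
#' @param measure `"LY"` or `"QALY"`.
#' @return A `cea_result` (with the per-strategy outcomes attached as
#'   attribute `"outcomes"`).
#' @export
scenario_utilities <- function(set_name, params,
                               strategies = default_strategies(),
                               measure = c("QALY", "LY")) {
  measure <- match.arg(measure)
  pp <- use_utility_set(params, set_name)
  res <- run_all_strategies(pp, strategies)
  out <- dominance_analysis(res, measure)
  attr(out, "outcomes") <- res
  out
}
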