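#' Round half away from zero
#'
#' Dollar figures and 4-decimal effect columns in the report tables use
#' commercial rounding (half away from zero), not banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

.eff_field <- function(measure) switch(measure, LY = "ly", QALY = "qaly",
                                       stop("measure must be 'LY' or 'QALY'"))

#' Incremental cost-effectiveness ratio between two strategies
#'
#' ICER = (cost_b - cost_a) / (eff_b - eff_a).  When the increments leave
#' the standard trade-off quadrant the function returns a flag instead of a
#' ratio: `"dominated"` (b costs more and is less effective than a),
#' `"dominant"` (b saves money and gains effectiveness), `"cost_saving"`
#' (less effective but cheaper -- a southwest move, reported with the
#' ratio), and `"undefined"` when the effectiveness increment is zero.
#'
#' @param a,b `strategy_outcome`s (or lists with `cost` and the measure
#'   field); `b` is compared against `a`.
#' @param measure `"LY"` or `"QALY"`.
#' @return List with `delta_cost`, `delta_eff`, `icer` (NA when flagged
#'   undefined/dominated/dominant) and `flag`.
#' @export
icer <- function(a, b, measure = c("QALY", "LY")) {
  measure <- match.arg(measure)
  f <- .eff_field(measure)
  dc <- b$cost - a$cost
  de <- b[[f]] - a[[f]]
  if (de == 0) {
    flag <- if (dc == 0) "identical" else "undefined"
    return(list(delta_cost = dc, delta_eff = de, icer = NA_real_, flag = flag))
  }
  flag <- if (de > 0 && dc >= 0) "icer"
  else if (de > 0 && dc < 0) "dominant"
  else if (de < 0 && dc > 0) "dominated"
  else "cost_saving"
  list(delta_cost = dc, delta_eff = de,
       icer = if (flag %in% c("icer", "cost_saving")) dc / de else NA_real_,
       flag = flag)
}

.outcomes_frame <- function(outcomes, measure) {
  f <- .eff_field(measure)
  data.frame(
    name = vapply(outcomes, function(o) o$strategy %||% "strategy", character(1)),
    cost = vapply(outcomes, function(o) o$cost, numeric(1)),
    eff = vapply(outcomes, function(o) o[[f]], numeric(1)),
    stringsAsFactors = FALSE)
}

#' Dominance analysis and efficiency frontier
#'
#' Sorts strategies by ascending effectiveness (ties broken by lower cost),
#' labels strategies strictly dominated by another (no more effective, no
#' cheaper, one strict), then iteratively removes extended-dominated
#' strategies until the incremental ICER ladder along the remaining chain
#' is strictly increasing.  The surviving chain is the efficiency frontier;
#' the optimal-strategy λ ranges follow from consecutive frontier ICERs:
#' the least effective frontier strategy is optimal on `[0, icer_1]` and
#' frontier strategy i on `(icer_i, icer_{i+1}]` (half-open, upper bound
#' included).
#'
#' @param outcomes List of `strategy_outcome`s (>= 2 for ICERs).
#' @param measure `"LY"` or `"QALY"`.
#' @return A `cea_result`: `table` (strategy, cost, eff, status, icer along
#'   the frontier), `frontier` (names in ascending effectiveness),
#'   `optimal_ranges` (lambda_low, lambda_high, strategy), and the pairwise
#'   ICER matrix `icer_matrix` (entry \[i, j\] compares j against the less
#'   effective i).
#' @export
dominance_analysis <- function(outcomes, measure = c("QALY", "LY")) {
  measure <- match.arg(measure)
  df <- .outcomes_frame(outcomes, measure)
  df <- df[order(df$eff, df$cost), , drop = FALSE]
  # exact ties in both dimensions collapse to one representative
  dup <- duplicated(df[, c("cost", "eff")])
  status <- ifelse(dup, "duplicate", "frontier")
  n <- nrow(df)

  for (i in seq_len(n)) {
    if (status[i] != "frontier") next
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$eff[j] >= df$eff[i] && df$cost[j] <= df$cost[i] &&
          (df$eff[j] > df$eff[i] || df$cost[j] < df$cost[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }

  repeat {
    keep <- which(status == "frontier")
    if (length(keep) < 3L) break
    ic <- diff(df$cost[keep]) / diff(df$eff[keep])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    status[keep[bad[1L] + 1L]] <- "extended_dominated"
  }

  keep <- which(status == "frontier")
  ladder <- rep(NA_real_, n)
  if (length(keep) > 1L)
    ladder[keep[-1L]] <- diff(df$cost[keep]) / diff(df$eff[keep])

  ranges <- NULL
  if (length(keep)) {
    lows <- c(0, ladder[keep[-1L]])
    highs <- c(ladder[keep[-1L]], Inf)
    ranges <- data.frame(lambda_low = lows, lambda_high = highs,
                         strategy = df$name[keep], stringsAsFactors = FALSE)
  }

  imat <- matrix(NA_real_, n, n, dimnames = list(df$name, df$name))
  flags <- matrix("", n, n, dimnames = list(df$name, df$name))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r2 <- {
      dc <- df$cost[j] - df$cost[i]; de <- df$eff[j] - df$eff[i]
      if (de > 0) list(icer = dc / de, flag = if (dc >= 0) "icer" else "dominant")
      else if (de == 0) list(icer = NA_real_, flag = "undefined")
      else list(icer = dc / de, flag = if (dc > 0) "dominated" else "cost_saving")
    }
    imat[i, j] <- if (r2$flag %in% c("icer", "cost_saving")) r2$icer else NA_real_
    flags[i, j] <- r2$flag
  }

  structure(list(measure = measure,
                 table = data.frame(df, status = status, icer = ladder,
                                    stringsAsFactors = FALSE, row.names = NULL),
                 frontier = df$name[keep],
                 optimal_ranges = ranges,
                 icer_matrix = imat, icer_flags = flags),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> measure %s\n", x$measure))
  print(x$table, digits = 6)
  invisible(x)
}

#' Optimal strategy at a willingness-to-pay ceiling
#'
#' The optimal strategy at ceiling ratio λ is the most effective frontier
#' strategy whose incremental ICER (against the previous frontier point) is
#' strictly below λ; for λ at or below the first frontier ICER this is the
#' least effective frontier strategy (no screening in the shipped set).
#'
#' @param cea A `cea_result` from [dominance_analysis()].
#' @param lambda Ceiling ratio in dollars per unit effectiveness.
#' @return The optimal strategy's name.
#' @export
optimal_strategy <- function(cea, lambda) {
  stopifnot(inherits(cea, "cea_result"), lambda >= 0)
  r <- cea$optimal_ranges
  hit <- which(lambda >= r$lambda_low & (lambda <= r$lambda_high |
                                           is.infinite(r$lambda_high)))
  # half-open (low, high]: an interior boundary belongs to the lower range
  r$strategy[hit[1L]]
}
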