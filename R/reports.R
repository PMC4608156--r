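# Report writers shaped like the published tables: per-strategy outcomes
# with increments vs no screening, the pairwise ICER matrix with dominance
# annotations, and the optimal-strategy lambda ranges; plus CEAC point
# export and a reproducibility manifest.

#' Per-strategy outcome table with increments vs no screening
#'
#' Strategies are sorted by ascending effectiveness (QALYs, then LYs);
#' increments are taken against the no-screening comparator.  Dollar
#' amounts are rounded to whole dollars and effects to four decimals, both
#' half away from zero.
#'
#' @param outcomes List of `strategy_outcome`s including the no-screening
#'   comparator.
#' @param comparator Name of the comparator strategy (default
#'   `"No screening"`).
#' @param digits_effect Decimals for LY/QALY columns.
#' @return Data frame with columns strategy, cost, inc_cost, ly, inc_ly,
#'   qaly, inc_qaly (comparator increments are zero).
#' @export
render_table1 <- function(outcomes, comparator = "No screening",
                          digits_effect = 4L) {
  nm <- vapply(outcomes, function(o) o$strategy, character(1))
  if (!comparator %in% nm)
    stop("outcome list must include the comparator '", comparator, "'",
         call. = FALSE)
  base <- outcomes[[match(comparator, nm)]]
  df <- data.frame(
    strategy = nm,
    cost = vapply(outcomes, function(o) o$cost, numeric(1)),
    ly = vapply(outcomes, function(o) o$ly, numeric(1)),
    qaly = vapply(outcomes, function(o) o$qaly, numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$qaly, df$ly), , drop = FALSE]
  out <- data.frame(
    strategy = df$strategy,
    cost = round_half_away(df$cost),
    inc_cost = round_half_away(df$cost - base$cost),
    ly = round_half_away(df$ly, digits_effect),
    inc_ly = round_half_away(df$ly - base$ly, digits_effect),
    qaly = round_half_away(df$qaly, digits_effect),
    inc_qaly = round_half_away(df$qaly - base$qaly, digits_effect),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Pairwise ICER matrix report
#'
#' @param cea A `cea_result` from [dominance_analysis()].
#' @return Data frame of the pairwise matrix (rows: less effective
#'   baseline; columns: comparison strategies) with ICERs rounded to whole
#'   dollars and dominance flags in place of meaningless ratios.
#' @export
render_icer_matrix <- function(cea) {
  m <- cea$icer_matrix
  fl <- cea$icer_flags
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (i == j) next
    out[i, j] <- if (fl[i, j] %in% c("icer", "cost_saving"))
      as.character(round_half_away(m[i, j])) else fl[i, j]
  }
  data.frame(strategy = rownames(out), out, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Optimal-strategy lambda ranges report
#'
#' @param cea A `cea_result`.
#' @return Data frame (lambda_low, lambda_high, strategy) with the
#'   boundaries rounded to whole dollars.
#' @export
render_optimal_ranges <- function(cea) {
  r <- cea$optimal_ranges
  data.frame(lambda_low = round_half_away(r$lambda_low),
             lambda_high = ifelse(is.infinite(r$lambda_high), Inf,
                                  round_half_away(r$lambda_high)),
             strategy = r$strategy, stringsAsFactors = FALSE)
}

#' Write a CEAC to CSV
#'
#' @param curve A `ceac_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ceac_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records what produced a set of outputs: a digest of the parameter
#' bundle, the strategy list, the seed(s), package version, timestamp and
#' settings snapshot.  Deterministic outputs re-run from the same manifest
#' reproduce byte-identically (timestamps aside).
#'
#' @param params The `crc_params` used.
#' @param strategies The strategy list used.
#' @param seed Seed(s) involved, if any.
#' @param extra Optional named list of additional settings to snapshot.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(params, strategies = default_strategies(),
                         seed = NULL, extra = list()) {
  tab <- parameter_table(params)
  digest <- sum(as.numeric(tab$value) *
                  (seq_along(tab$value) %% 97 + 1)) # order-sensitive checksum
  structure(list(
    package_version = as.character(utils::packageVersion("crcscreen")),
    timestamp = format(Sys.time(), tz = "UTC"),
    parameter_label = unclass(params)$meta$label %||% "unlabelled",
    parameter_digest = signif(digest, 15),
    n_parameters = nrow(tab),
    strategies = vapply(strategies, function(s) s$name, character(1)),
    seed = seed,
    econ = unclass(params)$econ,
    extra = extra), class = "run_manifest")
}

#' Write a manifest as JSON
#'
#' @param manifest A `run_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
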