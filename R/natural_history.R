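#' Annual other-cause mortality for a sex and age
#'
#' Non-cancer background mortality is the all-cause rate of the quinquennial
#' band containing `age` minus the registry colorectal-cancer rate of the
#' same band, clamped at zero (with a warning) should the cancer rate exceed
#' the all-cause rate.
#'
#' @param mortality Mortality table: data frame with columns `sex`,
#'   `age_band_start`, `age_band_end`, `all_cause_rate`, `crc_rate`.
#' @param sex `"male"` or `"female"` (any level present in the table).
#' @param age Attained age in years.
#' @return Annual probability of death from causes other than colorectal
#'   cancer or screening complications.
#' @export
other_cause_mortality <- function(mortality, sex, age) {
  sel <- mortality$sex == sex & mortality$age_band_start <= age &
    age <= mortality$age_band_end
  if (sum(sel) != 1L)
    stop(sprintf("no unique mortality band for sex '%s', age %s", sex, age),
         call. = FALSE)
  out <- mortality$all_cause_rate[sel] - mortality$crc_rate[sel]
  if (out < 0) {
    warning(sprintf(
      "cancer mortality exceeds all-cause mortality for %s aged %s; clamping to 0",
      sex, age))
    out <- 0
  }
  out
}

#' Read or write a mortality table as CSV
#'
#' @param path CSV file path.
#' @return For `read_mortality_csv`, the mortality data frame.
#' @export
read_mortality_csv <- function(path) {
  mt <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sex", "age_band_start", "age_band_end", "all_cause_rate", "crc_rate")
  if (!all(req %in% names(mt)))
    stop("mortality CSV needs columns: ", paste(req, collapse = ", "))
  mt
}

#' @rdname read_mortality_csv
#' @param mortality Mortality data frame to write.
#' @export
write_mortality_csv <- function(mortality, path) {
  utils::write.csv(mortality, path, row.names = FALSE)
  invisible(path)
}

#' Annual natural-history transition matrix
#'
#' Builds the 14-by-14 one-cycle transition matrix of the unscreened disease
#' process for a given attained age and sex.  Competing risks within the
#' cycle are resolved by sequential conditioning in the fixed order
#' death (cancer mortality for cancer states, then other-cause mortality for
#' all alive states), then symptomatic diagnosis, then at most one step of
#' disease progression.  Rows therefore sum to one exactly.  Symptomatic
#' presentation routes undiagnosed stage-k disease to the diagnosed stage-k
#' state with probability `p_symptomatic[k] * c_symptomatic`; diagnosed
#' disease no longer progresses; death states are absorbing.  Age enters
#' only through other-cause mortality.
#'
#' @param params A validated `crc_params` object.
#' @param age Attained age in years, within the model's age window.
#' @param sex `"male"` or `"female"`.
#' @return 14-by-14 matrix, rows and columns named by [health_states()];
#'   entry `[i, j]` is the probability of moving from state i to j in one
#'   annual cycle.
#' @export
build_transition_matrix <- function(params, age, sex) {
  ec <- params$econ
  if (age < ec$entry_age || age > ec$exit_age)
    stop(sprintf("age %s outside the model window [%d, %d]",
                 age, ec$entry_age, ec$exit_age), call. = FALSE)
  nh <- params$natural_history
  mo <- other_cause_mortality(params$mortality, sex, age)
  sym <- nh$p_symptomatic * params$compliance$c_symptomatic
  mc <- nh$m_crc
  pp <- c(nh$p_stage_progress, 0)  # stage IV does not progress further
  e <- nh$crc_entry_stage_dist

  T <- matrix(0, .N_STATE, .N_STATE, dimnames = list(.STATES, .STATES))

  # pre-cancer section: other-cause death, then one disease step
  T[.S_NORMAL, .S_DOTH] <- mo
  T[.S_NORMAL, .S_LOW] <- (1 - mo) * nh$p_normal_to_low
  T[.S_NORMAL, .S_NORMAL] <- (1 - mo) * (1 - nh$p_normal_to_low)

  T[.S_LOW, .S_DOTH] <- mo
  T[.S_LOW, .S_HIGH] <- (1 - mo) * nh$p_low_to_high
  T[.S_LOW, .S_LOW] <- (1 - mo) * (1 - nh$p_low_to_high)

  T[.S_HIGH, .S_DOTH] <- mo
  T[.S_HIGH, .S_UNDIAG] <- (1 - mo) * nh$p_high_to_crc * e
  T[.S_HIGH, .S_HIGH] <- (1 - mo) * (1 - nh$p_high_to_crc)

  for (k in 1:4) {
    su <- .S_UNDIAG[k]
    sd <- .S_DIAG[k]
    surv <- (1 - mc[k]) * (1 - mo)
    T[su, .S_DCRC] <- mc[k]
    T[su, .S_DOTH] <- (1 - mc[k]) * mo
    T[su, sd] <- surv * sym[k]
    if (k < 4) T[su, .S_UNDIAG[k + 1L]] <- surv * (1 - sym[k]) * pp[k]
    T[su, su] <- surv * (1 - sym[k]) * (1 - pp[k])

    T[sd, .S_DCRC] <- mc[k]
    T[sd, .S_DOTH] <- (1 - mc[k]) * mo
    T[sd, sd] <- surv
  }

  T[.S_DCRC, .S_DCRC] <- 1
  T[.S_DCOMP, .S_DCOMP] <- 1
  T[.S_DOTH, .S_DOTH] <- 1
  T
}

# transition matrices for every model cycle, reusing bands where the
# mortality lookup is constant
.transition_set <- function(params, sex) {
  ages <- params$econ$entry_age + seq_len(params$econ$horizon_years) - 1L
  mt <- params$mortality[params$mortality$sex == sex, , drop = FALSE]
  band <- vapply(ages, function(a)
    which(mt$age_band_start <= a & a <= mt$age_band_end)[1L], integer(1))
  cache <- vector("list", max(band))
  out <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    b <- band[i]
    if (is.null(cache[[b]]))
      cache[[b]] <- build_transition_matrix(params, ages[i], sex)
    out[[i]] <- cache[[b]]
  }
  out
}
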