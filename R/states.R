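#' Health-state space of the colorectal neoplasm model
#'
#' The model distinguishes 14 mutually exclusive health states organised in
#' four sections: pre-cancer (normal epithelium, low-risk polyps, high-risk
#' polyps), undiagnosed colorectal cancer by AJCC stage I--IV, diagnosed
#' cancer by stage, and three absorbing death states (cancer death, death
#' from endoscopic complications, death from other causes).
#'
#' @return Character vector of the 14 state identifiers, in model order.
#' @export
health_states <- function() {
  c("NORMAL", "LOW_RISK_POLYP", "HIGH_RISK_POLYP",
    "UNDIAG_CRC_I", "UNDIAG_CRC_II", "UNDIAG_CRC_III", "UNDIAG_CRC_IV",
    "DIAG_CRC_I", "DIAG_CRC_II", "DIAG_CRC_III", "DIAG_CRC_IV",
    "DEATH_CRC", "DEATH_COMPLICATION", "DEATH_OTHER")
}

# index helpers used throughout the engine
.STATES <- c("NORMAL", "LOW_RISK_POLYP", "HIGH_RISK_POLYP",
             "UNDIAG_CRC_I", "UNDIAG_CRC_II", "UNDIAG_CRC_III", "UNDIAG_CRC_IV",
             "DIAG_CRC_I", "DIAG_CRC_II", "DIAG_CRC_III", "DIAG_CRC_IV",
             "DEATH_CRC", "DEATH_COMPLICATION", "DEATH_OTHER")
.N_STATE  <- 14L
.S_NORMAL <- 1L
.S_LOW    <- 2L
.S_HIGH   <- 3L
.S_UNDIAG <- 4:7    # stages I..IV
.S_DIAG   <- 8:11   # stages I..IV
.S_DCRC   <- 12L
.S_DCOMP  <- 13L
.S_DOTH   <- 14L
.S_ALIVE  <- 1:11
.S_DEAD   <- 12:14
.S_PREDIAG <- 1:7   # states eligible for screening

#' Section membership of each health state
#'
#' @return Factor of length 14 with levels `pre_crc`, `undiagnosed_crc`,
#'   `diagnosed_crc`, `death`, aligned with [health_states()].
#' @export
state_sections <- function() {
  factor(c(rep("pre_crc", 3), rep("undiagnosed_crc", 4),
           rep("diagnosed_crc", 4), rep("death", 3)),
         levels = c("pre_crc", "undiagnosed_crc", "diagnosed_crc", "death"))
}

# Surveillance-track columns of the expanded occupancy.  Column 1 is the
# untracked population; low-risk post-polypectomy tracks carry a counter of
# years since the last colonoscopy (0..5, due at >= 5); the high-risk track
# is due every year.  low0 is only occupied transiently within a cycle
# (counter resets at the colonoscopy, then advances at cycle end).
.TRACKS  <- c("none", "low0", "low1", "low2", "low3", "low4", "low5", "high")
.N_TRACK <- 8L
.T_NONE  <- 1L
.T_LOW0  <- 2L
.T_LOW5  <- 7L
.T_HIGH  <- 8L
.LOW_INTERVAL  <- 5L
.HIGH_INTERVAL <- 1L

#' Surveillance track columns
#' @return Character vector naming the surveillance sub-states tracked
#'   alongside each health state (post-polypectomy colonoscopy schedules).
#' @export
surveillance_tracks <- function() .TRACKS

.track_col <- function(type, years) {
  switch(type,
         none = .T_NONE,
         high = .T_HIGH,
         low  = .T_LOW0 + min(as.integer(years), .LOW_INTERVAL),
         stop("unknown track type: ", type))
}

.track_of_col <- function(col) {
  if (col == .T_NONE) list(type = "none", years = NA_integer_)
  else if (col == .T_HIGH) list(type = "high", years = 1L)
  else list(type = "low", years = as.integer(col - .T_LOW0))
}

#' Define a screening strategy
#'
#' @param name Human-readable label.
#' @param test Primary screening instrument: `"none"`, `"gfobt"`, `"ifobt"`
#'   or `"colonoscopy"`.
#' @param interval_years Years between scheduled rounds (1, 2 or 10).
#' @param start_age,stop_age Age window (inclusive) in which rounds are
#'   offered.
#' @return An object of class `screening_strategy`.
#' @export
screening_strategy <- function(name, test = c("none", "gfobt", "ifobt", "colonoscopy"),
                               interval_years = 1L, start_age = 50L, stop_age = 74L) {
  test <- match.arg(test)
  stopifnot(interval_years >= 1, start_age <= stop_age)
  structure(list(name = name, test = test,
                 interval_years = as.integer(interval_years),
                 start_age = as.integer(start_age),
                 stop_age = as.integer(stop_age)),
            class = "screening_strategy")
}

#' @export
print.screening_strategy <- function(x, ...) {
  if (x$test == "none") cat(sprintf("<screening_strategy> %s (no scheduled rounds)\n", x$name))
  else cat(sprintf("<screening_strategy> %s: %s every %d year(s), ages %d-%d\n",
                   x$name, x$test, x$interval_years, x$start_age, x$stop_age))
  invisible(x)
}

#' The six comparator strategies
#'
#' No screening, annual/biennial guaiac FOBT, annual/biennial immunologic
#' FOBT, and colonoscopy every 10 years, offered from age 50 while the
#' cohort is under observation.
#'
#' @return Named list of six `screening_strategy` objects.
#' @export
default_strategies <- function() {
  list(
    none         = screening_strategy("No screening", "none"),
    gfobt_annual = screening_strategy("Annual G-FOBT", "gfobt", 1L),
    gfobt_biennial = screening_strategy("Biennial G-FOBT", "gfobt", 2L),
    ifobt_annual = screening_strategy("Annual I-FOBT", "ifobt", 1L),
    ifobt_biennial = screening_strategy("Biennial I-FOBT", "ifobt", 2L),
    colonoscopy_10y = screening_strategy("Colonoscopy every 10 years", "colonoscopy", 10L)
  )
}

#' Is a routine screening round due?
#'
#' A round is due when the strategy has a scheduled test, the attained age
#' falls inside the strategy's age window, and a whole number of intervals
#' has elapsed since the start age.
#'
#' @param strategy A `screening_strategy`.
#' @param age Attained age in years at the start of the cycle.
#' @return Logical.
#' @export
routine_round_due <- function(strategy, age) {
  strategy$test != "none" &&
    age >= strategy$start_age && age <= strategy$stop_age &&
    (age - strategy$start_age) %% strategy$interval_years == 0
}

#' Is a surveillance colonoscopy due for a track?
#'
#' Post-polypectomy surveillance is colonoscopy every 5 years on the
#' low-risk track and every year on the high-risk track.
#'
#' @param track List with elements `type` (`"low"` or `"high"`) and `years`
#'   (integer years since the last colonoscopy).
#' @param cycle_index Unused placeholder kept for interface symmetry with the
#'   screening kernel; due-ness depends only on the track clock.
#' @return Logical.
#' @export
surveillance_due <- function(track, cycle_index = NULL) {
  if (is.null(track$type) || track$type == "none")
    stop("surveillance_due() requires a surveillance track (type 'low' or 'high')")
  if (track$type == "high") track$years >= .HIGH_INTERVAL
  else track$years >= .LOW_INTERVAL
}
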