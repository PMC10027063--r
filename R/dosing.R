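#' Dosing schedule for a substrate
#'
#' Doses are intravenous boluses into the central compartment, given at
#' regular intervals until the simulation ends or the maximum number of
#' doses has been administered. The first `number_loading_doses` doses
#' carry the loading amount. The first dose is given either at a fixed
#' time (`set_first_dose_time = TRUE`) or at the first phenotype-step time
#' at which the measured 2D confluence reaches `confluence_condition`.
#'
#' Missing-parameter policy: `number_loading_doses` defaults to 0; the
#' loading amount defaults to the regular amount (with a warning);
#' `set_first_dose_time` defaults to `TRUE` with `first_dose_time = 0`.
#' A missing `central_increase_on_dose`, or a missing `dose_interval` when
#' more than one dose is requested, is an error.
#'
#' @param max_number_doses Maximum number of doses, loading included
#'   (integer >= 0).
#' @param dose_interval Minutes between consecutive doses (> 0; may be
#'   `NULL` when at most one dose is given).
#' @param central_increase_on_dose Circulation concentration increase per
#'   regular dose (a.u., >= 0).
#' @param number_loading_doses How many of the first doses are loading
#'   doses (integer, 0..`max_number_doses`).
#' @param central_increase_on_loading_dose Concentration increase per
#'   loading dose; defaults to the regular amount with a warning when
#'   loading doses are requested.
#' @param set_first_dose_time If `TRUE`, dosing starts at
#'   `first_dose_time`; if `FALSE`, dosing starts when confluence reaches
#'   `confluence_condition`.
#' @param first_dose_time Minutes (>= 0); used iff `set_first_dose_time`.
#' @param confluence_condition Proportion in \[0, 1\]; used iff
#'   `!set_first_dose_time`.
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(max_number_doses,
                          dose_interval = NULL,
                          central_increase_on_dose = NULL,
                          number_loading_doses = 0L,
                          central_increase_on_loading_dose = NULL,
                          set_first_dose_time = TRUE,
                          first_dose_time = 0,
                          confluence_condition = NULL) {
  stopifnot(is.numeric(max_number_doses), max_number_doses >= 0)
  max_number_doses <- as.integer(max_number_doses)
  number_loading_doses <- as.integer(number_loading_doses)
  if (number_loading_doses < 0 || number_loading_doses > max_number_doses)
    stop("number_loading_doses must be between 0 and max_number_doses")
  if (max_number_doses > 0L) {
    if (is.null(central_increase_on_dose))
      stop("central_increase_on_dose is required when doses are scheduled")
    if (central_increase_on_dose < 0)
      stop("central_increase_on_dose must be >= 0")
    if (max_number_doses > 1L) {
      if (is.null(dose_interval))
        stop("dose_interval is required when max_number_doses > 1")
      if (dose_interval <= 0)
        stop("dose_interval must be > 0 when max_number_doses > 1")
    }
  }
  if (number_loading_doses > 0L && is.null(central_increase_on_loading_dose)) {
    warning("central_increase_on_loading_dose missing; using the regular dose amount")
    central_increase_on_loading_dose <- central_increase_on_dose
  }
  if (!isTRUE(set_first_dose_time) && is.null(confluence_condition))
    stop("confluence_condition is required when set_first_dose_time is FALSE")
  if (!is.null(confluence_condition) &&
      (confluence_condition < 0 || confluence_condition > 1))
    stop("confluence_condition must be a proportion in [0, 1]")
  structure(list(max_number_doses = max_number_doses,
                 number_loading_doses = number_loading_doses,
                 dose_interval = dose_interval,
                 central_increase_on_dose = central_increase_on_dose,
                 central_increase_on_loading_dose = central_increase_on_loading_dose,
                 set_first_dose_time = isTRUE(set_first_dose_time),
                 first_dose_time = first_dose_time,
                 confluence_condition = confluence_condition),
            class = "dose_schedule")
}

#' Enumerate dose events for a resolved start time
#'
#' Events fall at `start_time + i * dose_interval` for
#' i = 0..(max_number_doses - 1), truncated at `t_end`; the first
#' `number_loading_doses` events carry the loading amount.
#'
#' @param schedule A [dose_schedule()].
#' @param start_time Time of the first dose (min), fixed or resolved by
#'   the confluence trigger.
#' @param t_end Simulation end time (min); events strictly after it are
#'   dropped.
#' @return A data frame with columns `time`, `amount`, `is_loading`,
#'   ordered by time.
#' @export
build_dose_times <- function(schedule, start_time, t_end = Inf) {
  stopifnot(inherits(schedule, "dose_schedule"))
  n <- schedule$max_number_doses
  if (n == 0L)
    return(data.frame(time = numeric(0), amount = numeric(0),
                      is_loading = logical(0)))
  interval <- if (n > 1L) schedule$dose_interval else 0
  times <- start_time + (seq_len(n) - 1L) * interval
  keep <- times <= t_end + 1e-9
  times <- times[keep]
  idx <- which(keep)
  is_loading <- idx <= schedule$number_loading_doses
  amount <- rep(as.numeric(schedule$central_increase_on_dose), length(idx))
  amount[is_loading] <- schedule$central_increase_on_loading_dose %||%
    schedule$central_increase_on_dose
  data.frame(time = times, amount = amount, is_loading = is_loading)
}

#' Resolve the time of the first dose
#'
#' With `set_first_dose_time = TRUE` the configured time is returned.
#' Otherwise the confluence series (measured at the phenotype time step)
#' is scanned for the first time at which confluence >= the threshold; the
#' realized first dose time therefore quantizes to the phenotype grid. If
#' confluence never reaches the threshold, `NA` is returned with a warning
#' and no doses are administered.
#'
#' @param schedule A [dose_schedule()].
#' @param confluence_series A data frame with columns `time` and
#'   `confluence` (rows in time order), as monitored at the phenotype time
#'   step; only consulted when `set_first_dose_time = FALSE`.
#' @return First dose time in minutes, or `NA_real_` if the trigger never
#'   fires.
#' @export
resolve_first_dose_time <- function(schedule, confluence_series = NULL) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (schedule$set_first_dose_time) return(schedule$first_dose_time)
  if (is.null(confluence_series))
    stop("confluence trigger requires a confluence series")
  hit <- which(confluence_series$confluence >= schedule$confluence_condition)
  if (!length(hit)) {
    warning("confluence condition never reached; no doses administered")
    return(NA_real_)
  }
  confluence_series$time[[hit[[1L]]]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
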