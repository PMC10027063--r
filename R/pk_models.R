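#' Systemic pharmacokinetic state
#'
#' Holds the circulation (central compartment) concentration, the periphery
#' concentration for two-compartment models, and the current time. All
#' concentrations are in arbitrary units (a.u.), times in minutes.
#'
#' @param circulation Central-compartment concentration (a.u., >= 0).
#' @param periphery Peripheral-compartment concentration, or `NULL` for
#'   one-compartment models.
#' @param time Current time in minutes.
#' @return An object of class `pk_state`.
#' @export
pk_state <- function(circulation = 0, periphery = NULL, time = 0) {
  stopifnot(is.numeric(circulation), length(circulation) == 1L,
            circulation >= 0)
  if (!is.null(periphery)) {
    stopifnot(is.numeric(periphery), length(periphery) == 1L, periphery >= 0)
  }
  structure(list(circulation = circulation, periphery = periphery,
                 time = time),
            class = "pk_state")
}

#' @export
print.pk_state <- function(x, ...) {
  cat(sprintf("pk_state @ t = %g min: C = %g", x$time, x$circulation))
  if (!is.null(x$periphery)) cat(sprintf(", P = %g", x$periphery))
  cat("\n")
  invisible(x)
}

#' One-compartment PK parameters
#'
#' The central compartment eliminates drug linearly: dC/dt = -lambda * C.
#'
#' @param elimination_rate Elimination rate lambda (1/min, >= 0).
#' @return An object of class `pk_1c_params`.
#' @export
one_compartment_params <- function(elimination_rate) {
  stopifnot(is.numeric(elimination_rate), length(elimination_rate) == 1L,
            is.finite(elimination_rate))
  if (elimination_rate < 0) stop("elimination_rate must be >= 0")
  structure(list(elimination_rate = elimination_rate),
            class = "pk_1c_params")
}

#' Two-compartment PK parameters
#'
#' Central and peripheral compartments exchange drug at clearance rates
#' `k12` (central to periphery) and `k21` (periphery to central); the
#' central compartment eliminates at rate lambda. `volume_ratio` R is the
#' ratio of central to peripheral compartment volumes, which makes the
#' exchange mass-conserving in concentration units:
#'
#'   dC/dt = (k21/R) P - k12 C - lambda C
#'   dP/dt = k12 R C - k21 P
#'
#' @param elimination_rate Elimination rate lambda (1/min, >= 0).
#' @param k12 Central-to-periphery clearance rate (1/min, >= 0).
#' @param k21 Periphery-to-central clearance rate (1/min, >= 0).
#' @param volume_ratio Central-to-peripheral volume ratio R (> 0).
#' @return An object of class `pk_2c_params`.
#' @export
two_compartment_params <- function(elimination_rate, k12, k21, volume_ratio) {
  vals <- c(elimination_rate, k12, k21, volume_ratio)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  if (elimination_rate < 0 || k12 < 0 || k21 < 0)
    stop("rates must be >= 0")
  if (volume_ratio <= 0) stop("volume_ratio must be > 0")
  structure(list(elimination_rate = elimination_rate, k12 = k12, k21 = k21,
                 volume_ratio = volume_ratio),
            class = "pk_2c_params")
}

#' Advance a one-compartment model by dt
#'
#' Exact update C' = C exp(-lambda dt); no integration error.
#'
#' @param state A [pk_state()].
#' @param params A [one_compartment_params()].
#' @param dt Step in minutes (>= 0).
#' @return The advanced `pk_state`.
#' @export
step_one_compartment <- function(state, params, dt) {
  stopifnot(inherits(state, "pk_state"), inherits(params, "pk_1c_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("dt must be a nonnegative finite number")
  if (dt == 0) return(state)
  state$circulation <- state$circulation * exp(-params$elimination_rate * dt)
  state$time <- state$time + dt
  state
}

#' Closed-form propagator of the two-compartment system
#'
#' Returns the 2x2 matrix exp(M dt) for
#' M = \[\[-(k12+lambda), k21/R\], \[k12 R, -k21\]\], computed by the
#' eigendecomposition closed form. The discriminant
#' tr^2 - 4 det = ((k12+lambda) - k21)^2 + 4 k12 k21 is always >= 0, so the
#' eigenvalues are real; when they (nearly) coincide
#' (disc < 1e-12 tr^2) the repeated-root limit
#' exp(mu dt) (I + dt (M - mu I)) is used to avoid catastrophic
#' cancellation.
#'
#' For a fixed dt the propagator can be computed once and passed to
#' [step_two_compartment()] for reuse; the reused matrix is bit-for-bit the
#' matrix a fresh computation would produce.
#'
#' @param params A [two_compartment_params()].
#' @param dt Step in minutes (> 0).
#' @return A 2x2 numeric matrix mapping c(C, P) at t to t + dt.
#' @export
two_compartment_propagator <- function(params, dt) {
  stopifnot(inherits(params, "pk_2c_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("dt must be a nonnegative finite number")
  k12 <- params$k12; k21 <- params$k21
  lam <- params$elimination_rate; R <- params$volume_ratio
  M <- matrix(c(-(k12 + lam), k12 * R, k21 / R, -k21), 2L, 2L)
  tr <- M[1L, 1L] + M[2L, 2L]
  dt_ <- M[1L, 1L] * M[2L, 2L] - M[1L, 2L] * M[2L, 1L]
  disc <- tr * tr - 4 * dt_
  I2 <- diag(2L)
  if (disc <= 1e-12 * tr * tr) {
    mu <- tr / 2
    exp(mu * dt) * (I2 + dt * (M - mu * I2))
  } else {
    s <- sqrt(disc)
    mu1 <- (tr + s) / 2
    mu2 <- (tr - s) / 2
    (exp(mu1 * dt) * (M - mu2 * I2) - exp(mu2 * dt) * (M - mu1 * I2)) /
      (mu1 - mu2)
  }
}

#' Advance a two-compartment model by dt
#'
#' Applies the closed-form propagator (see
#' [two_compartment_propagator()]); exact up to floating point, no
#' integration error. When lambda = 0 the quantity C + P/R is conserved.
#'
#' @param state A [pk_state()] with non-`NULL` periphery.
#' @param params A [two_compartment_params()].
#' @param dt Step in minutes (>= 0).
#' @param propagator Optional precomputed propagator matrix for this
#'   (params, dt) pair, as returned by [two_compartment_propagator()].
#' @return The advanced `pk_state`.
#' @export
step_two_compartment <- function(state, params, dt, propagator = NULL) {
  stopifnot(inherits(state, "pk_state"), inherits(params, "pk_2c_params"))
  if (is.null(state$periphery))
    stop("two-compartment step requires a periphery concentration")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("dt must be a nonnegative finite number")
  if (dt == 0) return(state)
  P <- if (is.null(propagator)) two_compartment_propagator(params, dt)
       else propagator
  v <- P %*% c(state$circulation, state$periphery)
  state$circulation <- v[1L]
  state$periphery <- v[2L]
  state$time <- state$time + dt
  state
}

#' Administer an intravenous bolus
#'
#' Instantaneously raises the circulation concentration by `amount`; the
#' periphery and the clock are untouched. Doses at the same instant are
#' additive.
#'
#' @param state A [pk_state()].
#' @param amount Concentration increase (a.u., >= 0).
#' @return The dosed `pk_state`.
#' @export
apply_dose <- function(state, amount) {
  stopifnot(inherits(state, "pk_state"))
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount) ||
      amount < 0)
    stop("dose amount must be a nonnegative finite number")
  state$circulation <- state$circulation + amount
  state
}

#' Simulate a compartmental PK model with a dosing schedule
#'
#' Steps the closed-form model on a fixed grid, applying any dose that falls
#' on a step boundary before the step over that interval (so a dose at t is
#' visible in the concentration reported at t).
#'
#' @param params A [one_compartment_params()] or [two_compartment_params()].
#' @param events A data frame of dose events with columns `time` and
#'   `amount` (see [build_dose_times()]), or `NULL` for no dosing.
#' @param t_end End time (min).
#' @param dt Reporting/step interval (min).
#' @param state Initial [pk_state()]; defaults to zero concentrations.
#' @return A data frame with columns `time_min`, `circulation`,
#'   `periphery` (`NA` for one-compartment models).
#' @export
simulate_pk <- function(params, events = NULL, t_end, dt = 1,
                        state = NULL) {
  two <- inherits(params, "pk_2c_params")
  if (is.null(state)) {
    state <- pk_state(0, periphery = if (two) 0 else NULL, time = 0)
  }
  n <- floor((t_end - state$time) / dt + 1e-9)
  prop <- if (two) two_compartment_propagator(params, dt) else NULL
  ev_t <- if (is.null(events)) numeric(0) else events$time
  ev_a <- if (is.null(events)) numeric(0) else events$amount
  next_ev <- 1L
  out_t <- numeric(n + 1L)
  out_c <- numeric(n + 1L)
  out_p <- numeric(n + 1L)
  record <- function(i) {
    out_t[i] <<- state$time
    out_c[i] <<- state$circulation
    out_p[i] <<- if (two) state$periphery else NA_real_
  }
  tol <- 1e-9
  for (i in seq_len(n + 1L)) {
    while (next_ev <= length(ev_t) && ev_t[next_ev] <= state$time + tol) {
      state <- apply_dose(state, ev_a[next_ev])
      next_ev <- next_ev + 1L
    }
    record(i)
    if (i <= n) {
      state <- if (two) step_two_compartment(state, params, dt, prop)
               else step_one_compartment(state, params, dt)
    }
  }
  data.frame(time_min = out_t, circulation = out_c, periphery = out_p)
}
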