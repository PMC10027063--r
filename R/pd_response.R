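# Pharmacodynamics: intracellular damage dynamics with closed-form
# updates, Hill-type effect factors, and multi-drug mechanism-of-action
# (MOA) combination.
#
# Per (substrate, cell type), the internalized substrate A is metabolized
# at rate m and feeds damage D, which is repaired at a linear rate r1 and
# a constant rate r0 (proportionality of A into D is 1):
#
#   dA/dt = -m A
#   dD/dt = A - r1 D - r0
#
# The update over a step of length t has the exact solution
#   A' = A e^{-m t}
#   D' = D e^{-r1 t} + A t e^{-r1 t} phi((r1 - m) t) - r0 t phi(-r1 t)
# where phi(x) = expm1(x)/x with phi(0) = 1. Writing the solution through
# phi makes the limit branches r1 = 0, m = 0 and m = r1 the continuous
# limits of the same arithmetic rather than special cases. D is clamped
# at 0 afterwards: damage is an abstract nonnegative quantity and the
# constant repair term would otherwise drive it negative at low A.

# expm1(x)/x, continuous through x = 0. Cubic Taylor term at |x| < 1e-5
# keeps the switch below double rounding error.
phi_expm1 <- function(x) {
  small <- abs(x) < 1e-5
  out <- x
  out[small] <- 1 + x[small] / 2 + x[small]^2 / 6
  out[!small] <- expm1(x[!small]) / x[!small]
  out
}

#' Damage-accumulation (PD) parameters for one (substrate, cell type) pair
#'
#' @param metabolism_rate Metabolism rate m of the internalized substrate
#'   (1/min, >= 0).
#' @param repair_rate_constant Zero-order damage repair rate r0
#'   (damage/min, >= 0).
#' @param repair_rate_linear First-order damage repair rate r1
#'   (1/min, >= 0).
#' @param dt PD time step in minutes (> 0); defaults to the mechanics step
#'   of the host simulation and must be a positive multiple of it.
#' @param damage_model `"AUC"` (damage driven by internalized
#'   concentration) or `"AUC_amount"` (driven by internalized amount).
#' @param precompute Whether the orchestrator may cache the update
#'   constants for this pair (disable when parameters vary per cell).
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(metabolism_rate, repair_rate_constant,
                      repair_rate_linear, dt = 0.1,
                      damage_model = c("AUC", "AUC_amount"),
                      precompute = TRUE) {
  damage_model <- match.arg(damage_model)
  vals <- c(metabolism_rate, repair_rate_constant, repair_rate_linear, dt)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals[1:3] < 0)) stop("PD rates must be >= 0")
  if (dt <= 0) stop("PD time step must be > 0")
  structure(list(metabolism_rate = metabolism_rate,
                 repair_rate_constant = repair_rate_constant,
                 repair_rate_linear = repair_rate_linear,
                 dt = dt, damage_model = damage_model,
                 precompute = isTRUE(precompute)),
            class = "pd_params")
}

#' Precompute closed-form PD update constants
#'
#' Caches the four constants of the closed-form update for a fixed step
#' so that millions of per-cell updates reduce to two fused
#' multiply-adds. Applying the precomputed update is bit-for-bit identical
#' to evaluating the closed form directly, because [pd_step()] routes both
#' paths through the same arithmetic.
#'
#' @param params A [pd_params()].
#' @param dt Step the constants are built for; defaults to `params$dt`.
#' @return An object of class `pd_precomputed` carrying the source
#'   parameters, the step, and the constants.
#' @export
pd_constants <- function(params, dt = params$dt) {
  stopifnot(inherits(params, "pd_params"))
  m <- params$metabolism_rate
  r1 <- params$repair_rate_linear
  r0 <- params$repair_rate_constant
  eD <- exp(-r1 * dt)
  structure(list(params = params, dt = dt,
                 decay_A = exp(-m * dt),
                 decay_D = eD,
                 transfer = dt * eD * phi_expm1((r1 - m) * dt),
                 repair0 = r0 * dt * phi_expm1(-r1 * dt)),
            class = "pd_precomputed")
}

#' Refresh cached PD constants if parameters or step changed
#'
#' Cache-coherence helper: returns `cached` untouched when it was built
#' from identical parameters and step, otherwise rebuilds.
#'
#' @param cached A `pd_precomputed` (or `NULL`).
#' @param params Current [pd_params()].
#' @param dt Current PD step.
#' @return A valid `pd_precomputed` for (params, dt).
#' @export
pd_refresh <- function(cached, params, dt = params$dt) {
  if (!is.null(cached) && inherits(cached, "pd_precomputed") &&
      identical(cached$params, params) && identical(cached$dt, dt))
    return(cached)
  pd_constants(params, dt)
}

#' Advance internalized substrate and damage by one PD step
#'
#' Exact (closed-form) update of the damage ODEs over the PD step; see the
#' model description in [pd_params()]. Accepts either raw parameters or a
#' [pd_constants()] object; both produce identical results. `A` and `D`
#' may be vectors (one entry per cell) sharing the same parameters.
#'
#' @param state A list with numeric fields `A` (internalized substrate)
#'   and `D` (damage), scalars or equal-length vectors.
#' @param params A [pd_params()] or [pd_constants()] object.
#' @return The updated state list; `D` is clamped at 0.
#' @export
pd_step <- function(state, params) {
  pre <- if (inherits(params, "pd_precomputed")) params
         else pd_constants(params)
  A <- state$A
  D <- state$D
  state$A <- A * pre$decay_A
  state$D <- pmax(0, D * pre$decay_D + A * pre$transfer - pre$repair0)
  state
}

#' Hill-type effect factor
#'
#' Maps damage to a multiplicative factor between 1 (no effect) and the
#' saturation factor `f_sat` (maximal effect):
#' `f = 1 + (f_sat - 1) (D/EC50)^n / (1 + (D/EC50)^n)`.
#' At D = 0 the factor is 1; at D = EC50 it is halfway between 1 and
#' `f_sat`; it is monotone in D and tends to `f_sat` as D grows.
#'
#' @param D Damage (>= 0); may be a vector.
#' @param EC50 Damage at half-maximal effect (> 0).
#' @param n Hill power (> 0).
#' @param f_sat Saturation factor (ratio of saturation to base rate).
#' @return Effect factor(s), same length as `D`.
#' @export
hill_factor <- function(D, EC50, n, f_sat) {
  if (!is.numeric(EC50) || EC50 <= 0) stop("EC50 must be > 0")
  if (!is.numeric(n) || n <= 0) stop("hill power must be > 0")
  x <- (D / EC50)^n
  1 + (f_sat - 1) * x / (1 + x)
}

# Saturating fraction (D/EC50)^n / (1 + (D/EC50)^n) in [0, 1); used for
# the additive necrosis form.
hill_fraction <- function(D, EC50, n) {
  x <- (D / EC50)^n
  x / (1 + x)
}

#' Mechanism-of-action configuration for one (substrate, cell type) pair
#'
#' Each entry activates one MOA with its saturation rate (the limiting
#' value of the targeted rate as damage grows), EC50 (damage at
#' half-effect) and Hill power. A missing Hill power defaults to 1 with a
#' warning; saturation rate and EC50 are required for every active MOA.
#'
#' @param prolif,apop,necrosis,motility Either `NULL` (MOA off) or a list
#'   with fields `saturation_rate` (1/min; um/min for motility), `EC50`
#'   (damage, > 0), and optional `hill_power` (> 0, default 1).
#' @return An object of class `moa_config`; a named list of active MOAs.
#' @export
moa_config <- function(prolif = NULL, apop = NULL, necrosis = NULL,
                       motility = NULL) {
  entries <- list(prolif = prolif, apop = apop, necrosis = necrosis,
                  motility = motility)
  entries <- entries[!vapply(entries, is.null, TRUE)]
  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (is.null(e$saturation_rate) || is.null(e$EC50))
      stop(sprintf("MOA '%s': saturation_rate and EC50 are required", nm))
    if (!is.numeric(e$EC50) || e$EC50 <= 0)
      stop(sprintf("MOA '%s': EC50 must be > 0", nm))
    if (is.null(e$hill_power)) {
      warning(sprintf("MOA '%s': hill_power missing, defaulting to 1", nm))
      e$hill_power <- 1
    }
    if (e$hill_power <= 0)
      stop(sprintf("MOA '%s': hill_power must be > 0", nm))
    entries[[nm]] <- e[c("saturation_rate", "EC50", "hill_power")]
  }
  structure(entries, class = "moa_config")
}

#' Apply drug mechanisms of action to a cell's phenotype rates
#'
#' First resets every targeted rate to its base value, then applies the
#' combined effect of all active (substrate, MOA) pairs, so repeated
#' application within a step does not stack effects. Proliferation,
#' apoptosis and motility speed are multiplicative: each substrate
#' contributes a Hill factor with `f_sat = saturation_rate / base_rate`
#' and the factors are multiplied. Necrosis is additive
#' (`base + sum_s saturation_rate_s * (D/EC50)^n / (1 + (D/EC50)^n)`)
#' because the base necrosis rate is commonly 0, which leaves `f_sat`
#' undefined; a multiplicative MOA on a zero base rate is a configuration
#' error caught at load.
#'
#' @param cell A list with a `base_rates` list (fields `prolif`, `apop`,
#'   `necrosis`, `motility`) and a `rates` list of the same shape.
#' @param active A list of active effects, each a list with fields `moa`
#'   (a [moa_config()]) and `state` (list with damage `D`), one per
#'   substrate acting on this cell.
#' @return The cell with `rates` recomputed from `base_rates`.
#' @export
apply_moas <- function(cell, active = list()) {
  base <- cell$base_rates
  rates <- base
  for (eff in active) {
    moa <- eff$moa
    D <- eff$state$D
    for (nm in names(moa)) {
      e <- moa[[nm]]
      if (nm == "necrosis") {
        rates$necrosis <- rates$necrosis +
          e$saturation_rate * hill_fraction(D, e$EC50, e$hill_power)
      } else {
        b <- base[[nm]]
        if (b == 0)
          stop(sprintf(
            "multiplicative MOA '%s' with base rate 0: f_sat is undefined; use the additive necrosis pattern",
            nm))
        rates[[nm]] <- rates[[nm]] *
          hill_factor(D, e$EC50, e$hill_power, e$saturation_rate / b)
      }
    }
  }
  cell$rates <- rates
  cell
}
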