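# Independent high-accuracy ODE oracles (adaptive lsoda at tight
# tolerances) for the closed-form compartment and damage updates, plus a
# brute-force dose-event enumerator. These never call the closed forms
# they are used to check.

oracle_1c <- function(C0, lambda, t_end) {
  sol <- deSolve::lsoda(c(C = C0), c(0, t_end),
                        function(t, y, p) list(-p * y), lambda,
                        rtol = 1e-12, atol = 1e-14)
  unname(sol[nrow(sol), "C"])
}

oracle_2c <- function(C0, P0, params, t_end) {
  f <- function(t, y, p) {
    with(as.list(p), list(c(
      k21 / R * y[2] - k12 * y[1] - lambda * y[1],
      k12 * R * y[1] - k21 * y[2])))
  }
  p <- c(lambda = params$elimination_rate, k12 = params$k12,
         k21 = params$k21, R = params$volume_ratio)
  sol <- deSolve::lsoda(c(C = C0, P = P0), c(0, t_end), f, p,
                        rtol = 1e-12, atol = 1e-14)
  unname(sol[nrow(sol), c("C", "P")])
}

# Damage ODE without the nonnegativity clamp.
oracle_pd <- function(A0, D0, m, r0, r1, t_end) {
  f <- function(t, y, p) {
    with(as.list(p), list(c(-m * y[1], y[1] - r1 * y[2] - r0)))
  }
  sol <- deSolve::lsoda(c(A = A0, D = D0), c(0, t_end), f,
                        c(m = m, r0 = r0, r1 = r1),
                        rtol = 1e-12, atol = 1e-14)
  unname(sol[nrow(sol), c("A", "D")])
}

# Uptake relaxation du/dt = -rho (Vc/Vv) u.
oracle_uptake <- function(u0, rho, vc_over_vv, t_end) {
  sol <- deSolve::lsoda(c(u = u0), c(0, t_end),
                        function(t, y, p) list(-p * y), rho * vc_over_vv,
                        rtol = 1e-12, atol = 1e-14)
  unname(sol[nrow(sol), "u"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(got, want) {
  abs(got - want) / pmax(abs(want), 1e-300)
}

# Straight-line enumeration of dose events from the schedule definition,
# independent of build_dose_times().
brute_force_doses <- function(schedule, start_time, t_end) {
  out <- list()
  for (i in seq_len(schedule$max_number_doses)) {
    t <- start_time +
      (i - 1) * (if (schedule$max_number_doses > 1) schedule$dose_interval else 0)
    if (t > t_end + 1e-9) break
    loading <- i <= schedule$number_loading_doses
    amt <- if (loading) {
      if (is.null(schedule$central_increase_on_loading_dose))
        schedule$central_increase_on_dose
      else schedule$central_increase_on_loading_dose
    } else schedule$central_increase_on_dose
    out[[i]] <- data.frame(time = t, amount = amt, is_loading = loading)
  }
  if (!length(out))
    return(data.frame(time = numeric(0), amount = numeric(0),
                      is_loading = logical(0)))
  do.call(rbind, out)
}

# Small drug-free test population on a few separated cells.
make_test_population <- function(n = 4, types = NULL,
                                 pd_substrates = character(0)) {
  if (is.null(types))
    types <- list(tumor = cell_type("tumor", radius = 10))
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cell_population(x = 100 * cos(ang), y = 100 * sin(ang),
                  type = names(types)[1], types = types,
                  pd_substrates = pd_substrates)
}

test_domain <- function()
  list(x_min = -400, x_max = 400, y_min = -400, y_max = 400)
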