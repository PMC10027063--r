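# SBML-defined PK models: a restricted SBML Level 2/3 core subset parsed
# with xml2 and integrated with deSolve. Supported constructs:
# compartments, parameters, species, rate rules, reactions whose kinetic
# law is an arithmetic (linear / mass-action) expression, and events with
# time-based triggers performing assignments. Anything else raises an
# unsupported-feature error naming the construct.

# Convert a MathML node to an R expression. `time_name` collects the
# symbol used for the time csymbol, mapped to .sbml_time.
mathml_to_r <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("malformed MathML: <math> must have one child")
    return(mathml_to_r(kids[[1L]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      txt <- trimws(vapply(parts, xml2::xml_text, ""))
      txt <- txt[nzchar(txt)]
      return(as.numeric(txt[1L]) * 10^as.numeric(txt[2L]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("symbols/time", url, fixed = TRUE))
      return(as.name(".sbml_time"))
    stop(sprintf("unsupported SBML construct: csymbol '%s'",
                 trimws(xml2::xml_text(node))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    args <- lapply(kids[-1L], mathml_to_r)
    fn <- switch(op,
                 plus = "+", minus = "-", times = "*", divide = "/",
                 power = "^", geq = ">=", gt = ">", leq = "<=", lt = "<",
                 exp = "exp", ln = "log",
                 stop(sprintf("unsupported SBML construct: MathML operator <%s>",
                              op)))
    if (fn %in% c("+", "*") && length(args) > 2L) {
      e <- args[[1L]]
      for (k in 2L:length(args)) e <- call(fn, e, args[[k]])
      return(e)
    }
    if (fn == "-" && length(args) == 1L) return(call("-", args[[1L]]))
    return(as.call(c(as.name(fn), args)))
  }
  stop(sprintf("unsupported SBML construct: MathML element <%s>", nm))
}

# Extract the trigger time from a trigger expression of the form
# time >= T (or >, or the mirrored T <= time).
sbml_trigger_time <- function(expr) {
  bad <- function() stop(
    "unsupported SBML construct: event trigger must compare time against a constant")
  if (!is.call(expr) || length(expr) != 3L) bad()
  op <- as.character(expr[[1L]])
  lhs <- expr[[2L]]; rhs <- expr[[3L]]
  is_time <- function(e) is.name(e) && as.character(e) == ".sbml_time"
  if (op %in% c(">=", ">") && is_time(lhs) && is.numeric(rhs)) return(rhs)
  if (op %in% c("<=", "<") && is.numeric(lhs) && is_time(rhs)) return(lhs)
  bad()
}

#' Load an SBML-defined PK model
#'
#' Parses an SBML Level 2/3 core file into an ODE model whose circulation
#' readout drives the Dirichlet boundary coupling. The readout is the
#' species named `circulation_concentration` if one exists, otherwise the
#' first listed species. Supported: compartments, global parameters,
#' species with initial concentrations/amounts, rate rules, reactions with
#' arithmetic kinetic laws (including local parameters), and events whose
#' triggers are time comparisons and whose assignments are arithmetic.
#' Dosing must be encoded as events inside the file. Unsupported constructs
#' (algebraic rules, assignment rules, delays, function definitions)
#' produce an error naming the construct.
#'
#' Model time is assumed to be minutes unless the model declares
#' `timeUnits` of seconds, in which case rates and event times are
#' converted.
#'
#' @param path Path to an SBML file.
#' @return An object of class `sbml_pk_model`: a self-contained ODE system
#'   with pending events, a designated circulation readout, and a clock.
#' @seealso [step_sbml_pk()], [sbml_circulation()], [make_toy_sbml()]
#' @export
load_sbml_pk <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element in SBML file")

  unsupported <- c(listOfFunctionDefinitions = "function definitions",
                   algebraicRule = "algebraic rules",
                   assignmentRule = "assignment rules",
                   delay = "event delays")
  for (tag in names(unsupported)) {
    if (!inherits(xml2::xml_find_first(doc, paste0(".//", tag)),
                  "xml_missing"))
      stop(sprintf("unsupported SBML construct: %s", unsupported[[tag]]))
  }

  time_units <- xml2::xml_attr(model, "timeUnits")
  time_scale <- 1
  if (!is.na(time_units)) {
    if (time_units %in% c("second", "seconds")) time_scale <- 60
    else if (!time_units %in% c("minute", "minutes", "time")) {
      stop(sprintf("unsupported SBML construct: time unit '%s'", time_units))
    }
  }

  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  compartments <- vapply(comp_nodes, function(n) {
    sz <- xml2::xml_attr(n, "size")
    if (is.na(sz)) 1 else as.numeric(sz)
  }, 0)
  names(compartments) <- xml2::xml_attr(comp_nodes, "id")

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  params <- vapply(par_nodes, function(n) {
    v <- xml2::xml_attr(n, "value")
    if (is.na(v)) 0 else as.numeric(v)
  }, 0)
  names(params) <- xml2::xml_attr(par_nodes, "id")

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("SBML model declares no species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_init <- vapply(sp_nodes, function(n) {
    v <- xml2::xml_attr(n, "initialConcentration")
    if (is.na(v)) v <- xml2::xml_attr(n, "initialAmount")
    if (is.na(v)) 0 else as.numeric(v)
  }, 0)
  names(sp_init) <- sp_id
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  names(sp_comp) <- sp_id
  sp_const <- xml2::xml_attr(sp_nodes, "constant") %in% "true" |
    xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  names(sp_const) <- sp_id

  derivs <- stats::setNames(vector("list", length(sp_id)), sp_id)

  rate_nodes <- xml2::xml_find_all(doc, ".//listOfRules/rateRule")
  for (n in rate_nodes) {
    var <- xml2::xml_attr(n, "variable")
    if (!var %in% sp_id)
      stop(sprintf("rate rule for unknown species '%s'", var))
    derivs[[var]] <- mathml_to_r(xml2::xml_find_first(n, "./math"))
  }

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rxn_nodes, function(n) {
    kl <- xml2::xml_find_first(n, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("unsupported SBML construct: reaction without kineticLaw")
    lp_nodes <- xml2::xml_find_all(
      kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
    lp <- stats::setNames(as.numeric(xml2::xml_attr(lp_nodes, "value")),
                          xml2::xml_attr(lp_nodes, "id"))
    get_refs <- function(xp) {
      nodes <- xml2::xml_find_all(n, xp)
      ids <- xml2::xml_attr(nodes, "species")
      st <- xml2::xml_attr(nodes, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      stats::setNames(st, ids)
    }
    list(rate = mathml_to_r(xml2::xml_find_first(kl, "./math")),
         local = lp,
         reactants = get_refs("./listOfReactants/speciesReference"),
         products = get_refs("./listOfProducts/speciesReference"))
  })

  ev_nodes <- xml2::xml_find_all(doc, ".//listOfEvents/event")
  events <- lapply(ev_nodes, function(n) {
    trig <- xml2::xml_find_first(n, "./trigger/math")
    if (inherits(trig, "xml_missing")) stop("event without trigger math")
    t_ev <- sbml_trigger_time(mathml_to_r(trig)) / time_scale
    asg_nodes <- xml2::xml_find_all(n, ".//eventAssignment")
    assignments <- lapply(asg_nodes, function(a) {
      list(variable = xml2::xml_attr(a, "variable"),
           expr = mathml_to_r(xml2::xml_find_first(a, "./math")))
    })
    list(time = t_ev, assignments = assignments)
  })
  if (length(events) > 1L) {
    ord <- order(vapply(events, `[[`, 0, "time"))
    events <- events[ord]
    tt <- vapply(events, `[[`, 0, "time")
    if (any(diff(tt) <= 0))
      stop("event trigger times must be strictly increasing")
  }

  readout <- if ("circulation_concentration" %in% sp_id)
    "circulation_concentration" else sp_id[[1L]]

  structure(list(species = sp_init, species_compartment = sp_comp,
                 species_constant = sp_const, compartments = compartments,
                 params = params, derivs = derivs, reactions = rxns,
                 events = events,
                 fired = rep(FALSE, length(events)),
                 readout = readout, time = 0, time_scale = time_scale),
            class = "sbml_pk_model")
}

#' @export
print.sbml_pk_model <- function(x, ...) {
  cat(sprintf("sbml_pk_model: %d species, %d reactions, %d rate rules, %d events\n",
              length(x$species), length(x$reactions),
              sum(!vapply(x$derivs, is.null, TRUE)), length(x$events)))
  cat(sprintf("  readout: %s = %g @ t = %g min\n", x$readout,
              x$species[[x$readout]], x$time))
  invisible(x)
}

#' Circulation readout of an SBML PK model
#'
#' @param model An `sbml_pk_model`.
#' @return The current value of the designated circulation species.
#' @export
sbml_circulation <- function(model) {
  stopifnot(inherits(model, "sbml_pk_model"))
  unname(model$species[[model$readout]])
}

# Build the deSolve right-hand side closure for a model.
sbml_rhs <- function(model) {
  base_env <- list2env(c(as.list(model$params),
                         as.list(model$compartments)),
                       parent = baseenv())
  sp_id <- names(model$species)
  function(t, y, parms) {
    env <- list2env(as.list(y), parent = base_env)
    env$.sbml_time <- t * model$time_scale
    dy <- stats::setNames(numeric(length(sp_id)), sp_id)
    for (s in sp_id) {
      if (!is.null(model$derivs[[s]])) dy[[s]] <- eval(model$derivs[[s]], env)
    }
    for (rx in model$reactions) {
      renv <- if (length(rx$local))
        list2env(as.list(rx$local), parent = env) else env
      rate <- eval(rx$rate, renv)
      for (s in names(rx$reactants)) {
        vol <- model$compartments[[model$species_compartment[[s]]]]
        dy[[s]] <- dy[[s]] - rx$reactants[[s]] * rate / vol
      }
      for (s in names(rx$products)) {
        vol <- model$compartments[[model$species_compartment[[s]]]]
        dy[[s]] <- dy[[s]] + rx$products[[s]] * rate / vol
      }
    }
    dy[model$species_constant] <- 0
    list(dy * model$time_scale)
  }
}

sbml_apply_event <- function(model, ev) {
  env <- list2env(c(as.list(model$species), as.list(model$params),
                    as.list(model$compartments)),
                  parent = baseenv())
  env$.sbml_time <- model$time * model$time_scale
  for (a in ev$assignments) {
    val <- eval(a$expr, env)
    if (a$variable %in% names(model$species)) {
      model$species[[a$variable]] <- val
    } else if (a$variable %in% names(model$params)) {
      model$params[[a$variable]] <- val
    } else {
      stop(sprintf("event assigns unknown variable '%s'", a$variable))
    }
    assign(a$variable, val, envir = env)
  }
  model
}

#' Advance an SBML PK model by dt
#'
#' Integrates the model's ODEs with an adaptive-step integrator
#' (deSolve's lsoda, rtol 1e-10). Events whose trigger times fall inside
#' the step are applied at their exact trigger times: integration is split
#' at each event, the assignments applied, and integration resumed. Each
#' event fires at most once over the model's lifetime.
#'
#' @param model An `sbml_pk_model` from [load_sbml_pk()].
#' @param dt Step in minutes (>= 0).
#' @return The advanced `sbml_pk_model`.
#' @export
step_sbml_pk <- function(model, dt) {
  stopifnot(inherits(model, "sbml_pk_model"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("dt must be a nonnegative finite number")
  # dt = 0 is allowed: it fires events triggered exactly now
  target <- model$time + dt
  tol <- 1e-9
  rhs <- sbml_rhs(model)
  integrate_to <- function(model, t1) {
    if (t1 - model$time > tol) {
      sol <- deSolve::lsoda(y = model$species,
                            times = c(model$time, t1),
                            func = rhs, parms = NULL,
                            rtol = 1e-10, atol = 1e-12)
      if (attr(sol, "istate")[1L] < 0)
        stop("SBML ODE integration failed (lsoda diagnostic istate < 0)")
      model$species[] <- sol[nrow(sol), names(model$species)]
    }
    model$time <- t1
    model
  }
  if (length(model$events)) {
    ev_times <- vapply(model$events, `[[`, 0, "time")
    due <- which(!model$fired & ev_times > model$time - tol &
                   ev_times <= target + tol)
    for (i in due) {
      model <- integrate_to(model, min(max(ev_times[[i]], model$time), target))
      model <- sbml_apply_event(model, model$events[[i]])
      model$fired[[i]] <- TRUE
      rhs <- sbml_rhs(model)  # params may have changed
    }
  }
  integrate_to(model, target)
}

#' Simulate an SBML PK model over a time grid
#'
#' Convenience wrapper around [step_sbml_pk()] recording the circulation
#' readout at each grid time.
#'
#' @param model An `sbml_pk_model`.
#' @param times Increasing vector of times (min), starting at the model's
#'   current time.
#' @return A data frame with columns `time_min` and `circulation`.
#' @export
simulate_sbml_pk <- function(model, times) {
  stopifnot(inherits(model, "sbml_pk_model"), length(times) >= 1L)
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    model <- step_sbml_pk(model, max(0, times[i] - model$time))
    out[i] <- sbml_circulation(model)
  }
  data.frame(time_min = times, circulation = out)
}
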