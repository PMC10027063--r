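# Orchestration: configuration loading/validation with a
# warn-and-default / hard-error policy, the main time-stepping loop
# wiring PK -> Dirichlet -> diffusion/uptake -> PD -> MOA ->
# phenotype/mechanics, logging, and plain-text outputs.
#
# Within one diffusion interval the event order is fixed: doses due at
# the interval start are applied to the circulation first, then the PK
# model is advanced, the Dirichlet boundary is refreshed from the new
# circulation value, the field diffuses/decays, and cells exchange with
# the field. Mechanics-cadence work (PD updates, MOA application, cell
# mechanics) and phenotype-cadence work (division/death, confluence
# monitoring, snapshots) run at the end of the intervals that close a
# mechanics or phenotype step.

#' Assemble a simulation configuration programmatically
#'
#' The programmatic equivalent of [load_config()]: all parts are supplied
#' as ready-made objects. Call [validate_config()] (done automatically by
#' [run_simulation()]) to check cross-references and time-step
#' divisibility.
#'
#' @param domain List with `x_min`, `x_max`, `y_min`, `y_max` (um),
#'   `voxel_size` (um), optional `thickness`.
#' @param time List with `diffusion_dt`, `mechanics_dt`, `phenotype_dt`,
#'   `t_end` (minutes). Mechanics must be a multiple of diffusion and
#'   phenotype a multiple of mechanics.
#' @param substrates Named list; each entry a list with
#'   `diffusion_coefficient`, `decay_rate`, optional
#'   `initial_concentration`, `dirichlet_edges`, `biot_number`,
#'   `pk_model` (`"1C"`, `"2C"`, `"SBML"` or `NULL` for no PK),
#'   `pk_params` ([one_compartment_params()] / [two_compartment_params()]),
#'   `sbml_file`, and `schedule` ([dose_schedule()]).
#' @param cell_types Named list of [cell_type()] definitions.
#' @param initial_cells A data frame with columns `x`, `y`, `cell_type`,
#'   or a list `list(kind = "disc", n =, radius =, cell_type =)` resolved
#'   at run time under the run seed, or `NULL` for no cells.
#' @param pk_substrates,pd_substrates Character vectors naming which
#'   substrates follow a PK model and which exert PD effects; they need
#'   not coincide.
#' @param seed Integer RNG seed.
#' @param snapshot_interval Minutes between recorded snapshots
#'   (`Inf` for final-state only).
#' @param precompute_all_pd Cache PD update constants per
#'   (substrate, cell type) pair; individual pairs can override via their
#'   [pd_params()] `precompute` flag.
#' @return An object of class `pkpd_config`.
#' @export
simulation_config <- function(domain, time, substrates = list(),
                              cell_types = list(), initial_cells = NULL,
                              pk_substrates = character(0),
                              pd_substrates = character(0),
                              seed = 0L, snapshot_interval = 360,
                              precompute_all_pd = TRUE) {
  structure(list(domain = domain, time = time, substrates = substrates,
                 cell_types = cell_types, initial_cells = initial_cells,
                 pk_substrates = pk_substrates,
                 pd_substrates = pd_substrates,
                 seed = as.integer(seed),
                 snapshot_interval = snapshot_interval,
                 precompute_all_pd = isTRUE(precompute_all_pd),
                 load_log = character(0), validated = FALSE),
            class = "pkpd_config")
}

#' Validate a simulation configuration
#'
#' Checks cross-references (every PK/PD substrate name refers to a
#' declared substrate, every MOA/PD block refers to a declared
#' substrate), time-step divisibility, and per-module invariants
#' (EC50 > 0, multiplicative MOAs on nonzero base rates, PD steps
#' positive multiples of the mechanics step). All problems are reported
#' together in a single error.
#'
#' @param config A `pkpd_config`.
#' @return The validated config (idempotent).
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pkpd_config"))
  if (isTRUE(config$validated)) return(config)
  errs <- character(0)
  tm <- config$time
  for (f in c("diffusion_dt", "mechanics_dt", "phenotype_dt", "t_end"))
    if (is.null(tm[[f]]) || tm[[f]] <= 0)
      errs <- c(errs, sprintf("time$%s must be set and > 0", f))
  if (!length(errs)) {
    me <- tm$mechanics_dt / tm$diffusion_dt
    pe <- tm$phenotype_dt / tm$mechanics_dt
    if (abs(me - round(me)) > 1e-8)
      errs <- c(errs, "mechanics_dt must be a multiple of diffusion_dt")
    if (abs(pe - round(pe)) > 1e-8)
      errs <- c(errs, "phenotype_dt must be a multiple of mechanics_dt")
  }
  sn <- names(config$substrates)
  for (s in config$pk_substrates)
    if (!s %in% sn)
      errs <- c(errs, sprintf("PK substrate '%s' is not a declared substrate", s))
  for (s in config$pd_substrates)
    if (!s %in% sn)
      errs <- c(errs, sprintf("PD substrate '%s' is not a declared substrate", s))
  for (s in config$pk_substrates) {
    sub <- config$substrates[[s]]
    if (is.null(sub)) next
    model <- sub$pk_model %||% "2C"
    if (!model %in% c("1C", "2C", "SBML"))
      errs <- c(errs, sprintf("substrate '%s': unknown pk model '%s'", s, model))
    if (model == "1C" && !inherits(sub$pk_params, "pk_1c_params"))
      errs <- c(errs, sprintf("substrate '%s': 1C model needs one_compartment_params", s))
    if (model == "2C" && !inherits(sub$pk_params, "pk_2c_params"))
      errs <- c(errs, sprintf("substrate '%s': 2C model needs two_compartment_params", s))
    if (model == "SBML" && is.null(sub$sbml_file))
      errs <- c(errs, sprintf("substrate '%s': SBML model needs sbml_file", s))
    if (!is.null(sub$biot_number) && sub$biot_number < 0)
      errs <- c(errs, sprintf("substrate '%s': Biot number must be >= 0", s))
  }
  for (ct in names(config$cell_types)) {
    tdef <- config$cell_types[[ct]]
    if (!inherits(tdef, "cell_type_def")) {
      errs <- c(errs, sprintf("cell type '%s' is not a cell_type()", ct))
      next
    }
    for (s in names(tdef$pd)) {
      if (!s %in% sn)
        errs <- c(errs, sprintf("cell type '%s': PD block for unknown substrate '%s'", ct, s))
      pdp <- tdef$pd[[s]]
      k <- pdp$dt / tm$mechanics_dt
      if (k <= 0 || abs(k - round(k)) > 1e-8)
        errs <- c(errs, sprintf(
          "cell type '%s', substrate '%s': PD step must be a positive multiple of mechanics_dt",
          ct, s))
    }
    for (s in names(tdef$moa)) {
      if (!s %in% sn)
        errs <- c(errs, sprintf("cell type '%s': MOA block for unknown substrate '%s'", ct, s))
      moa <- tdef$moa[[s]]
      for (nm in names(moa)) {
        if (nm != "necrosis") {
          b <- switch(nm, prolif = tdef$prolif_rate, apop = tdef$apop_rate,
                      motility = tdef$motility_speed)
          if (b == 0)
            errs <- c(errs, sprintf(
              "cell type '%s', substrate '%s': multiplicative MOA '%s' with base rate 0 (f_sat undefined); use the additive necrosis pattern",
              ct, s, nm))
        }
      }
      if (!s %in% names(tdef$pd))
        errs <- c(errs, sprintf(
          "cell type '%s': MOA for substrate '%s' without a PD block", ct, s))
    }
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  config$validated <- TRUE
  config
}

# --- YAML configuration ----------------------------------------------

# Pull "<prefix>_<key>" out of a named list; NULL when absent.
pref_get <- function(block, prefix, key) block[[paste0(prefix, "_", key)]]

#' Load and validate a YAML simulation configuration
#'
#' The file is hierarchical YAML whose leaf keys follow the standard
#' parameter-naming convention with the substrate name substituted for S,
#' the cell type for C, and the MOA for X (for example
#' `drugA_central_elimination_rate` under the `drugA` substrate block, or
#' `drugA_prolif_EC50` under a cell type's `custom_data`). The
#' comma-separated user parameters `PKPD_pk_substrate_names` and
#' `PKPD_pd_substrate_names` select which substrates follow PK and PD
#' models.
#'
#' Policy for missing parameters: defaults are used with a warning where
#' a sensible default exists (PK model `"2C"`, Biot number 1, damage
#' model `"AUC"`, Hill power 1, zero loading doses, first dose at time
#' 0), and errors are raised where no default is defensible (dose amount,
#' dose interval with multiple doses, the three damage-accumulation
#' rates, saturation rate and EC50 of an active MOA). All errors are
#' listed at once. Every defaulted parameter is reported exactly once.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `pkpd_config`; defaulting warnings are also stored
#'   in its `load_log` field.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  warns <- character(0)
  errs <- character(0)
  note <- function(msg) warns <<- c(warns, msg)
  bad <- function(msg) errs <<- c(errs, msg)

  up <- raw$user_parameters %||% list()
  split_names <- function(x) {
    if (is.null(x) || !nzchar(x)) character(0)
    else trimws(strsplit(as.character(x), ",")[[1L]])
  }
  pk_names <- split_names(up$PKPD_pk_substrate_names)
  pd_names <- split_names(up$PKPD_pd_substrate_names)
  precompute_all <- up$PKPD_precompute_all_pd_quantities %||% TRUE

  substrates <- list()
  for (s in names(raw$substrates %||% list())) {
    blk <- raw$substrates[[s]]
    entry <- list(
      diffusion_coefficient = blk$diffusion_coefficient %||% 6e4,
      decay_rate = blk$decay_rate %||% 0,
      initial_concentration = blk$initial_concentration %||% 0,
      dirichlet_edges = as.character(blk$dirichlet_edges %||% character(0)))
    if (s %in% pk_names) {
      model <- pref_get(blk, s, "pk_model")
      if (is.null(model)) {
        model <- "2C"
        note(sprintf("%s_pk_model missing; defaulting to the two-compartment model", s))
      }
      biot <- pref_get(blk, s, "biot_number")
      if (is.null(biot)) {
        biot <- 1
        note(sprintf("%s_biot_number missing; defaulting to 1", s))
      }
      entry$pk_model <- model
      entry$biot_number <- biot
      getd <- function(key, default = NULL) {
        v <- pref_get(blk, s, key)
        if (is.null(v) && !is.null(default)) {
          note(sprintf("%s_%s missing; defaulting to %g", s, key, default))
          v <- default
        }
        v
      }
      if (identical(model, "1C")) {
        entry$pk_params <- one_compartment_params(
          getd("central_elimination_rate", 0))
      } else if (identical(model, "2C")) {
        entry$pk_params <- two_compartment_params(
          elimination_rate = getd("central_elimination_rate", 0),
          k12 = getd("central_to_periphery_clearance_rate", 0),
          k21 = getd("periphery_to_central_clearance_rate", 0),
          volume_ratio = getd("central_to_periphery_volume_ratio", 1))
      } else if (identical(model, "SBML")) {
        entry$sbml_file <- pref_get(blk, s, "sbml_file")
        if (is.null(entry$sbml_file))
          bad(sprintf("%s_sbml_file is required for an SBML-defined PK model", s))
      } else {
        bad(sprintf("substrate '%s': unknown pk model string '%s'", s, model))
      }
      if (!identical(model, "SBML")) {
        maxd <- pref_get(blk, s, "max_number_doses") %||% 0L
        if (maxd > 0) {
          amount <- pref_get(blk, s, "central_increase_on_dose")
          if (is.null(amount)) {
            bad(sprintf("%s_central_increase_on_dose is required", s))
            amount <- 0
          }
          interval <- pref_get(blk, s, "dose_interval")
          if (maxd > 1 && is.null(interval))
            bad(sprintf("%s_dose_interval is required when %s_max_number_doses > 1", s, s))
          nload <- pref_get(blk, s, "number_loading_doses") %||% 0L
          lamount <- pref_get(blk, s, "central_increase_on_loading_dose")
          if (nload > 0 && is.null(lamount)) {
            note(sprintf("%s_central_increase_on_loading_dose missing; using the regular dose amount", s))
            lamount <- amount
          }
          setf <- pref_get(blk, s, "set_first_dose_time")
          conf <- pref_get(blk, s, "confluence_condition")
          first <- pref_get(blk, s, "first_dose_time")
          if (is.null(setf)) {
            setf <- TRUE
            if (is.null(first)) {
              first <- 0
              note(sprintf("%s_set_first_dose_time missing; defaulting to a first dose at time 0", s))
            }
          }
          if (isTRUE(setf) && is.null(first)) {
            first <- 0
            note(sprintf("%s_first_dose_time missing; defaulting to 0", s))
          }
          if (!isTRUE(setf) && is.null(conf))
            bad(sprintf("%s_confluence_condition is required when %s_set_first_dose_time is false", s, s))
          if (!length(errs))
            entry$schedule <- dose_schedule(
              max_number_doses = maxd,
              dose_interval = interval,
              central_increase_on_dose = amount,
              number_loading_doses = nload,
              central_increase_on_loading_dose = lamount,
              set_first_dose_time = isTRUE(setf),
              first_dose_time = first %||% 0,
              confluence_condition = conf)
        }
      }
    }
    substrates[[s]] <- entry
  }

  cell_types <- list()
  for (ct in names(raw$cell_types %||% list())) {
    blk <- raw$cell_types[[ct]]
    cd <- blk$custom_data %||% list()
    uptake <- unlist(blk$uptake %||% list())
    pd <- list()
    moa <- list()
    for (s in pd_names) {
      has_any <- any(grepl(paste0("^", s, "_"), names(cd)))
      if (!has_any) next
      model <- cd[[sprintf("%s_on_%s_pd_model", s, ct)]]
      if (is.null(model)) {
        model <- "AUC"
        note(sprintf("%s_on_%s_pd_model missing; defaulting to the concentration-based model (AUC)", s, ct))
      }
      req <- function(key) {
        v <- cd[[paste0(s, "_", key)]]
        if (is.null(v)) {
          bad(sprintf("%s_%s is required in custom_data of cell type '%s'", s, key, ct))
          0
        } else v
      }
      pd_dt <- cd[[sprintf("%s_dt_%s", s, ct)]] %||% raw$time$mechanics_dt %||% 0.1
      pre <- cd[[sprintf("%s_precompute_pd_for_%s", s, ct)]] %||% precompute_all
      pd[[s]] <- pd_params(metabolism_rate = req("metabolism_rate"),
                           repair_rate_constant = req("repair_rate_constant"),
                           repair_rate_linear = req("repair_rate_linear"),
                           dt = pd_dt, damage_model = model,
                           precompute = isTRUE(pre))
      margs <- list()
      for (x in c("prolif", "apop", "necrosis", "motility")) {
        flag <- cd[[sprintf("%s_moa_is_%s", s, x)]] %||% 0
        if (as.numeric(flag) > 0.5) {  # custom data are doubles; > 0.5 means true
          e <- list(saturation_rate = cd[[sprintf("%s_%s_saturation_rate", s, x)]],
                    EC50 = cd[[sprintf("%s_%s_EC50", s, x)]],
                    hill_power = cd[[sprintf("%s_%s_hill_power", s, x)]])
          if (is.null(e$saturation_rate) || is.null(e$EC50)) {
            bad(sprintf("MOA '%s' of %s on %s: saturation_rate and EC50 are required", x, s, ct))
            next
          }
          if (is.null(e$hill_power)) {
            note(sprintf("%s_%s_hill_power missing; defaulting to 1", s, x))
            e$hill_power <- 1
          }
          if (e$EC50 <= 0)
            bad(sprintf("MOA '%s' of %s on %s: EC50 must be > 0", x, s, ct))
          margs[[x]] <- e
        }
      }
      unknown <- setdiff(grep(paste0("^", s, "_moa_is_"), names(cd), value = TRUE),
                         sprintf("%s_moa_is_%s", s, c("prolif", "apop", "necrosis", "motility")))
      for (u in unknown)
        bad(sprintf("unknown MOA name in key '%s'", u))
      if (length(margs) && !length(errs))
        moa[[s]] <- suppressWarnings(do.call(moa_config, margs))
    }
    cell_types[[ct]] <- cell_type(
      name = ct,
      radius = blk$radius %||% 10,
      prolif_rate = blk$prolif_rate %||% 0,
      apop_rate = blk$apop_rate %||% 0,
      necrosis_rate = blk$necrosis_rate %||% 0,
      motility_speed = blk$motility_speed %||% 0,
      persistence_time = blk$persistence_time %||% 5,
      uptake = uptake, pd = pd, moa = moa)
  }

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))

  ic <- raw$initial_cells
  if (!is.null(ic) && is.character(ic)) ic <- utils::read.csv(ic)
  if (!is.null(ic) && is.list(ic) && !is.data.frame(ic)) {
    # YAML 1.1 reads a bare key `n` as the boolean FALSE
    names(ic)[names(ic) %in% c("FALSE", "n")] <- "n_cells"
    if (is.null(ic$kind) && !is.null(ic$x)) ic <- as.data.frame(ic)
  }

  config <- simulation_config(
    domain = raw$domain,
    time = raw$time,
    substrates = substrates,
    cell_types = cell_types,
    initial_cells = ic,
    pk_substrates = pk_names,
    pd_substrates = pd_names,
    seed = raw$seed %||% 0L,
    snapshot_interval = raw$output$snapshot_interval %||% 360,
    precompute_all_pd = isTRUE(precompute_all))
  config$load_log <- warns
  for (w in warns) warning(w, call. = FALSE)
  validate_config(config)
}

# Resolve the initial layout (possibly a generator spec) into a data
# frame; called after the run seed is set so generated layouts are
# reproducible per run.
resolve_initial_cells <- function(config) {
  ic <- config$initial_cells
  if (is.null(ic))
    return(data.frame(x = numeric(0), y = numeric(0),
                      cell_type = character(0)))
  if (is.data.frame(ic)) return(ic)
  if (identical(ic$kind, "disc")) {
    ctype <- ic$cell_type %||% names(config$cell_types)[[1L]]
    r_cell <- config$cell_types[[ctype]]$radius
    return(make_initial_tumor(ic$n_cells %||% ic$n, ic$radius,
                              cell_type = ctype, cell_radius = r_cell))
  }
  stop("unknown initial_cells specification")
}

#' Run a full simulation
#'
#' Executes the coupled PK / microenvironment / PD / agent loop described
#' in the package vignette. Per diffusion step: doses due at the interval
#' start are applied, the systemic PK advances, the Dirichlet boundary is
#' refreshed as Biot number times circulation, the field diffuses and
#' decays, and cells take up drug. Per mechanics step: damage updates for
#' every (cell, PD substrate) pair honoring per-pair PD steps, MOA
#' application, and cell mechanics. Per phenotype step: division/death,
#' confluence monitoring (which may trigger the first dose), and
#' snapshots. Fully deterministic given the seed.
#'
#' @param config A `pkpd_config` from [simulation_config()] or
#'   [load_config()].
#' @param seed Optional seed override.
#' @param t_end Optional end-time override (min).
#' @param output_dir If non-`NULL`, plain-text outputs
#'   (`pk_trajectory.csv`, `doses.csv`, `snapshots/`, `summary.csv`,
#'   `run.log`) are written there.
#' @return An object of class `pkpd_run`: final `cells` and `grid`, dose
#'   log, PK trajectory, confluence series, snapshots, event log, and the
#'   resolved config.
#' @export
run_simulation <- function(config, seed = NULL, t_end = NULL,
                           output_dir = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(t_end)) config$time$t_end <- t_end
  set.seed(config$seed)
  dom <- config$domain
  tm <- config$time
  run_log <- character(0)
  add_log <- function(t, msg)
    run_log <<- c(run_log, sprintf("[t=%10.2f min] %s", t, msg))
  for (w in config$load_log) add_log(0, paste("warning:", w))

  grid <- microenv(dom$x_min, dom$x_max, dom$y_min, dom$y_max,
                   dom$voxel_size, dom$thickness %||% dom$voxel_size)
  for (s in names(config$substrates)) {
    sub <- config$substrates[[s]]
    grid <- add_substrate(grid, s, sub$diffusion_coefficient,
                          sub$decay_rate, sub$initial_concentration %||% 0,
                          sub$dirichlet_edges %||% character(0))
  }

  layout <- resolve_initial_cells(config)
  cells <- cell_population(layout$x, layout$y, as.character(layout$cell_type),
                           config$cell_types, config$pd_substrates)

  dt_d <- tm$diffusion_dt
  m_every <- as.integer(round(tm$mechanics_dt / dt_d))
  p_every <- as.integer(round(tm$phenotype_dt / dt_d))
  n_steps <- as.integer(round(tm$t_end / dt_d))
  snap_every <- if (is.finite(config$snapshot_interval))
    max(1L, as.integer(round(config$snapshot_interval / dt_d))) else NA_integer_

  # systemic PK runtime state per PK substrate
  pk <- list()
  events <- list()
  ev_ptr <- list()
  pending_confluence <- character(0)
  for (s in config$pk_substrates) {
    sub <- config$substrates[[s]]
    model <- sub$pk_model %||% "2C"
    st <- switch(model,
                 "1C" = list(kind = "1C", C = 0, P = NA_real_,
                             decay = exp(-sub$pk_params$elimination_rate * dt_d)),
                 "2C" = list(kind = "2C", C = 0, P = 0,
                             prop = two_compartment_propagator(sub$pk_params, dt_d)),
                 "SBML" = list(kind = "SBML",
                               model = load_sbml_pk(sub$sbml_file)))
    st$biot <- sub$biot_number %||% 1
    pk[[s]] <- st
    sch <- sub$schedule
    ev_ptr[[s]] <- 1L
    if (!is.null(sch) && sch$max_number_doses > 0) {
      if (sch$set_first_dose_time) {
        events[[s]] <- build_dose_times(sch, sch$first_dose_time, tm$t_end)
      } else {
        pending_confluence <- c(pending_confluence, s)
      }
    }
  }

  # PD firing cadence per (cell type, substrate), in mechanics steps
  pd_every <- list()
  pd_cache <- list()
  for (ct in names(config$cell_types)) {
    tdef <- config$cell_types[[ct]]
    for (s in names(tdef$pd)) {
      pdp <- tdef$pd[[s]]
      key <- paste(ct, s, sep = "\r")
      pd_every[[key]] <- as.integer(round(pdp$dt / tm$mechanics_dt))
      use_pre <- pdp$precompute && config$precompute_all_pd
      pd_cache[[key]] <- if (use_pre) pd_constants(pdp) else NULL
    }
  }

  dose_rows <- list()
  snapshots <- list()
  event_totals <- c(n_division = 0L, n_apoptosis = 0L, n_necrosis = 0L)

  # preallocated PK trajectory (recorded at t = 0 and every mechanics step)
  n_pk <- length(config$pk_substrates)
  n_mech_total <- n_steps %/% m_every
  pk_cap <- (n_mech_total + 1L) * max(n_pk, 1L)
  pk_rec <- list(t = numeric(pk_cap), s = character(pk_cap),
                 C = numeric(pk_cap), P = rep(NA_real_, pk_cap), i = 0L)
  # preallocated confluence series (t = 0 and every phenotype step)
  n_phen_total <- n_steps %/% p_every
  conf_rec <- list(t = numeric(n_phen_total + 1L),
                   conf = numeric(n_phen_total + 1L),
                   n = integer(n_phen_total + 1L), i = 0L)

  take_snapshot <- function(t) {
    snapshots[[length(snapshots) + 1L]] <<-
      list(time = t, cells = cells_snapshot_df(cells, config),
           field = field_snapshot(grid),
           profiles = do.call(rbind, lapply(names(grid$substrates), function(s)
             cbind(substrate = s, xavg_profile(grid, s)))))
  }
  record_pk <- function(t) {
    for (s in names(pk)) {
      st <- pk[[s]]
      i <- pk_rec$i + 1L
      pk_rec$i <<- i
      pk_rec$t[i] <<- t
      pk_rec$s[i] <<- s
      pk_rec$C[i] <<- if (st$kind == "SBML") sbml_circulation(st$model) else st$C
      pk_rec$P[i] <<- if (st$kind == "2C") st$P else NA_real_
    }
  }
  record_conf <- function(t, cf) {
    i <- conf_rec$i + 1L
    conf_rec$i <<- i
    conf_rec$t[i] <<- t
    conf_rec$conf[i] <<- cf
    conf_rec$n[i] <<- ncells(cells)
  }

  # Uptake bookkeeping cached between position/population changes: per
  # substrate, the per-cell voxel index, uptake rates, volumes, the
  # per-voxel implicit-relaxation denominator, and the units conversion
  # of internalized mass (1 for amount-based, 1/volume for
  # concentration-based). Rebuilt after every mechanics/phenotype step.
  ex_cache <- NULL
  n_vox <- grid$nx * grid$ny
  rebuild_ex_cache <- function() {
    if (!ncells(cells)) {
      ex_cache <<- NULL
      return(invisible())
    }
    upt <- uptake_by_cell(cells)
    upt <- upt[names(upt) %in% names(grid$substrates)]
    if (!length(upt)) {
      ex_cache <<- NULL
      return(invisible())
    }
    lin <- voxel_index(grid, cells$x, cells$y)
    vol <- cell_volumes(cells)
    dm <- damage_model_by_cell(cells, names(upt))
    cache <- list()
    for (s in names(upt)) {
      rho <- upt[[s]]
      scale_i <- dt_d * rho * vol / grid$voxel_volume
      denom <- numeric(n_vox)
      acc <- rowsum(scale_i, lin)
      denom[as.integer(rownames(acc))] <- acc[, 1L]
      cache[[s]] <- list(lin = lin, rho = rho, vol = vol, denom = denom,
                         conv = ifelse(dm[[s]] == "AUC_amount", 1, 1 / vol),
                         col = match(s, cells$pd_substrates))
    }
    ex_cache <<- cache
  }

  mech_count <- 0L
  take_snapshot(0)
  record_pk(0)
  record_conf(0, confluence(cells, dom))
  rebuild_ex_cache()
  tol <- 1e-9

  for (step in seq_len(n_steps)) {
    t0 <- (step - 1L) * dt_d
    t1 <- step * dt_d
    # (1) doses due at the interval start, before the PK step
    for (s in names(events)) {
      ev <- events[[s]]
      while (!is.null(ev) && ev_ptr[[s]] <= nrow(ev) &&
             ev$time[ev_ptr[[s]]] <= t0 + tol) {
        i <- ev_ptr[[s]]
        st <- pk[[s]]
        if (st$kind == "SBML")
          stop("dose schedules do not apply to SBML-defined PK models")
        pk[[s]]$C <- st$C + ev$amount[i]
        dose_rows[[length(dose_rows) + 1L]] <-
          data.frame(time_min = ev$time[i], substrate = s,
                     amount = ev$amount[i], is_loading = ev$is_loading[i])
        add_log(t0, sprintf("dose of %g a.u. of %s administered%s",
                            ev$amount[i], s,
                            if (ev$is_loading[i]) " (loading)" else ""))
        ev_ptr[[s]] <- i + 1L
      }
    }
    # (2) advance systemic PK, refresh Dirichlet boundaries
    for (s in names(pk)) {
      st <- pk[[s]]
      if (st$kind == "1C") {
        st$C <- st$C * st$decay
      } else if (st$kind == "2C") {
        v <- st$prop %*% c(st$C, st$P)
        st$C <- v[1L]; st$P <- v[2L]
      } else {
        st$model <- step_sbml_pk(st$model, dt_d)
      }
      pk[[s]] <- st
      C <- if (st$kind == "SBML") sbml_circulation(st$model) else st$C
      sub <- grid$substrates[[s]]
      if (any(sub$dmask)) {
        val <- st$biot * C
        sub$dval[sub$dmask] <- val
        sub$u[sub$dmask] <- val
        grid$substrates[[s]] <- sub
      }
    }
    # (3) diffusion/decay, (4) cellular uptake (implicit voxel sink; same
    # arithmetic as exchange_with_cells, with the geometry cached)
    grid <- diffuse_decay_step(grid, dt_d)
    if (!is.null(ex_cache)) {
      for (s in names(ex_cache)) {
        cc <- ex_cache[[s]]
        sub <- grid$substrates[[s]]
        unew <- sub$u / (1 + cc$denom)
        gained <- unew[cc$lin] * dt_d * cc$rho * cc$vol
        unew[sub$dmask] <- sub$dval[sub$dmask]
        grid$substrates[[s]]$u <- unew
        if (!is.na(cc$col))
          cells$A[, cc$col] <- cells$A[, cc$col] + gained * cc$conv
      }
    }
    # mechanics-cadence work
    if (step %% m_every == 0L) {
      mech_count <- mech_count + 1L
      if (ncells(cells) && length(cells$pd_substrates)) {
        for (tix in seq_along(cells$types)) {
          tdef <- cells$types[[tix]]
          ct <- names(cells$types)[[tix]]
          for (s in names(tdef$pd)) {
            key <- paste(ct, s, sep = "\r")
            if (mech_count %% pd_every[[key]] != 0L) next
            sel <- cells$type == tix
            if (!any(sel)) next
            k <- match(s, cells$pd_substrates)
            pre <- pd_cache[[key]] %||% pd_constants(tdef$pd[[s]])
            stt <- pd_step(list(A = cells$A[sel, k], D = cells$D[sel, k]), pre)
            cells$A[sel, k] <- stt$A
            cells$D[sel, k] <- stt$D
          }
        }
        cells <- apply_moas_population(cells)
      }
      cells <- mechanics_step(cells, tm$mechanics_dt, dom)
      record_pk(t1)
      if (step %% p_every != 0L) rebuild_ex_cache()
    }
    # phenotype-cadence work
    if (step %% p_every == 0L) {
      res <- phenotype_step(cells, tm$phenotype_dt, dom)
      cells <- res$cells
      event_totals <- event_totals + unlist(res$events)
      cf <- confluence(cells, dom)
      record_conf(t1, cf)
      if (length(pending_confluence)) {
        for (s in pending_confluence) {
          sch <- config$substrates[[s]]$schedule
          if (cf >= sch$confluence_condition) {
            events[[s]] <- build_dose_times(sch, t1, tm$t_end)
            add_log(t1, sprintf(
              "confluence %.3f reached threshold %.3f; dosing of %s starts",
              cf, sch$confluence_condition, s))
            pending_confluence <- setdiff(pending_confluence, s)
          }
        }
      }
      rebuild_ex_cache()
      if (!is.na(snap_every) && step %% snap_every == 0L) take_snapshot(t1)
    }
  }
  if (length(pending_confluence)) {
    for (s in pending_confluence) {
      msg <- sprintf("confluence condition for %s never reached; zero doses administered", s)
      add_log(tm$t_end, msg)
      warning(msg, call. = FALSE)
    }
  }
  last_snap_t <- if (length(snapshots)) snapshots[[length(snapshots)]]$time
                 else -1
  if (abs(last_snap_t - tm$t_end) > tol) take_snapshot(tm$t_end)

  ii <- seq_len(pk_rec$i)
  jj <- seq_len(conf_rec$i)
  result <- structure(list(
    cells = cells, grid = grid, config = config,
    doses = if (length(dose_rows)) do.call(rbind, dose_rows) else
      data.frame(time_min = numeric(0), substrate = character(0),
                 amount = numeric(0), is_loading = logical(0)),
    pk_trajectory = if (pk_rec$i) data.frame(
      time_min = pk_rec$t[ii], substrate = pk_rec$s[ii],
      circulation = pk_rec$C[ii], periphery = pk_rec$P[ii]) else NULL,
    confluence = data.frame(time = conf_rec$t[jj],
                            confluence = conf_rec$conf[jj],
                            n_cells = conf_rec$n[jj]),
    snapshots = snapshots,
    events = as.list(event_totals),
    log = run_log), class = "pkpd_run")
  if (!is.null(output_dir)) write_outputs(result, output_dir)
  result
}

#' @export
print.pkpd_run <- function(x, ...) {
  cat(sprintf("pkpd_run: %d cells at t = %g min; %d dose(s); %d snapshot(s)\n",
              ncells(x$cells), x$config$time$t_end, nrow(x$doses),
              length(x$snapshots)))
  cat(sprintf("  events: %d divisions, %d apoptoses, %d necroses\n",
              x$events$n_division, x$events$n_apoptosis, x$events$n_necrosis))
  invisible(x)
}

cell_volumes <- function(cells) {
  unname(vapply(cells$types, `[[`, 0, "volume")[cells$type])
}

# Per-substrate uptake vectors over cells, from the type definitions.
uptake_by_cell <- function(cells) {
  subs <- unique(unlist(lapply(cells$types, function(t) names(t$uptake))))
  out <- list()
  for (s in subs) {
    rho <- unname(vapply(cells$types,
                         function(t) t$uptake[s] %|na|% 0, 0)[cells$type])
    if (any(rho > 0)) out[[s]] <- rho
  }
  out
}

# Per-substrate vectors of "AUC"/"AUC_amount" over cells, from the type
# PD declarations (default concentration-based).
damage_model_by_cell <- function(cells, substrates) {
  out <- list()
  for (s in substrates) {
    out[[s]] <- unname(vapply(cells$types, function(t) {
      if (!is.null(t$pd[[s]])) t$pd[[s]]$damage_model else "AUC"
    }, "")[cells$type])
  }
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Cells snapshot as a data frame, including damage-based coloring over
# the first (up to two) PD substrates.
cells_snapshot_df <- function(cells, config) {
  n <- ncells(cells)
  df <- data.frame(id = cells$id,
                   type = names(cells$types)[cells$type],
                   x_um = cells$x, y_um = cells$y,
                   prolif_rate = cells$rate_prolif,
                   apop_rate = cells$rate_apop,
                   necrosis_rate = cells$rate_necrosis,
                   motility_speed = cells$speed)
  for (k in seq_along(cells$pd_substrates)) {
    s <- cells$pd_substrates[[k]]
    df[[paste0("A_", s)]] <- cells$A[, k]
    df[[paste0("D_", s)]] <- cells$D[, k]
  }
  show <- utils::head(cells$pd_substrates, 2L)
  if (length(show) && n) {
    ec <- vapply(show, function(s) {
      for (t in config$cell_types)
        for (m in t$moa[[s]]) if (!is.null(m$EC50)) return(m$EC50)
      1
    }, 0)
    k1 <- match(show[1L], cells$pd_substrates)
    rgb <- if (length(show) == 2L)
      damage_coloring(cells$D[, k1], ec[1L],
                      cells$D[, match(show[2L], cells$pd_substrates)], ec[2L])
    else damage_coloring(cells$D[, k1], ec[1L])
    df$color_r <- rgb[, "r"]; df$color_g <- rgb[, "g"]; df$color_b <- rgb[, "b"]
  }
  df
}

#' Summarize a run's snapshots
#'
#' Per snapshot time: cell counts by type and, per PD substrate, the mean
#' and SD of log10(damage) over cells with positive damage only (times
#' with no positively-damaged cells are `NA`, not -Inf).
#'
#' @param run A `pkpd_run`.
#' @return A data frame with one row per snapshot.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "pkpd_run"))
  type_names <- names(run$config$cell_types)
  pd_subs <- run$config$pd_substrates
  rows <- lapply(run$snapshots, function(sn) {
    df <- sn$cells
    row <- data.frame(time_min = sn$time, n_cells = nrow(df))
    for (tn in type_names)
      row[[paste0("n_", tn)]] <- sum(df$type == tn)
    for (s in pd_subs) {
      d <- df[[paste0("D_", s)]]
      d <- d[!is.na(d) & d > 0]
      row[[paste0("mean_log10_damage_", s)]] <-
        if (length(d)) mean(log10(d)) else NA_real_
      row[[paste0("sd_log10_damage_", s)]] <-
        if (length(d) > 1) stats::sd(log10(d)) else
          if (length(d) == 1) 0 else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Write a run's outputs as plain-text files
#'
#' Writes `pk_trajectory.csv`, `doses.csv`, `summary.csv`, `run.log`, and
#' per-snapshot `snapshots/cells_t<min>.csv` / `snapshots/field_t<min>.csv`.
#' All output is deterministic given the run, so identical runs produce
#' byte-identical files.
#'
#' @param run A `pkpd_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "pkpd_run"))
  dir.create(file.path(dir, "snapshots"), recursive = TRUE,
             showWarnings = FALSE)
  wcsv <- function(df, path)
    utils::write.csv(df, file.path(dir, path), row.names = FALSE)
  if (!is.null(run$pk_trajectory)) wcsv(run$pk_trajectory, "pk_trajectory.csv")
  wcsv(run$doses, "doses.csv")
  wcsv(run$confluence, "confluence.csv")
  wcsv(summarize_run(run), "summary.csv")
  for (sn in run$snapshots) {
    tag <- sprintf("t%08.1f", sn$time)
    wcsv(sn$cells, file.path("snapshots", sprintf("cells_%s.csv", tag)))
    wcsv(sn$field, file.path("snapshots", sprintf("field_%s.csv", tag)))
  }
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}
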