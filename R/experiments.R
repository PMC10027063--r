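# Packaged sample experiments (one per mechanism of action, a
# combination therapy, a confluence-triggered start, and an SBML-defined
# PK run), fixture generators (toy SBML files, disc tumor layouts), and
# the dose-sweep harness for IC50-style curves. All samples run at
# reduced scale (800 um domain, ~200 initial cells) so a full 48 h
# simulated course completes in seconds to minutes on one CPU.

SAMPLE_NAMES <- c("prolif_sample", "apop_sample", "necrosis_sample",
                  "motility_sample", "combo_sample",
                  "confluence_start_sample", "sbml_pk_sample",
                  "template_1C", "template_2C")

#' List packaged sample experiments
#'
#' @return Character vector of sample names accepted by
#'   [sample_config()] and [run_sample()].
#' @export
list_samples <- function() SAMPLE_NAMES

# Shared reduced-scale pieces -----------------------------------------

sample_domain <- function()
  list(x_min = -400, x_max = 400, y_min = -400, y_max = 400,
       voxel_size = 20, thickness = 20)

sample_time <- function(t_end = 2880)
  list(diffusion_dt = 0.1, mechanics_dt = 1, phenotype_dt = 6,
       t_end = t_end)

# Two-compartment plasma kinetics with a ~70 min central half-life and
# symmetric distribution; three maintenance doses 12 h apart by default.
sample_pk_entry <- function(drug = "drugA", schedule = NULL,
                            model = "2C") {
  entry <- list(
    diffusion_coefficient = 6e4, decay_rate = 0.01,
    dirichlet_edges = "bottom",
    pk_model = model, biot_number = 1)
  if (model == "1C") {
    entry$pk_params <- one_compartment_params(0.01)
  } else if (model == "2C") {
    entry$pk_params <- two_compartment_params(
      elimination_rate = 0.01, k12 = 0.005, k21 = 0.005, volume_ratio = 1)
  }
  entry$schedule <- schedule %||% dose_schedule(
    max_number_doses = 3, dose_interval = 720,
    central_increase_on_dose = 10,
    set_first_dose_time = TRUE, first_dose_time = 0)
  entry
}

# Damage accumulation shared by the samples: metabolism half-life
# ~14 min, slow linear repair (tau ~200 min), small constant repair.
sample_pd <- function(dt = 1, damage_model = "AUC")
  pd_params(metabolism_rate = 0.05, repair_rate_constant = 1e-4,
            repair_rate_linear = 0.005, dt = dt,
            damage_model = damage_model)

sample_tumor <- function(drug = "drugA", moa = list(), extra_uptake = NULL,
                         pd = NULL) {
  uptake <- stats::setNames(rep(0.02, length(moa) + length(extra_uptake)),
                            c(names(moa), names(extra_uptake)))
  pd_list <- pd %||% stats::setNames(
    lapply(names(moa), function(s) sample_pd()), names(moa))
  cell_type("tumor", radius = 10,
            prolif_rate = 5e-4,   # ~23 h doubling
            apop_rate = 5e-5,     # long natural lifetime
            necrosis_rate = 0,
            motility_speed = 0.25,
            persistence_time = 5,
            uptake = uptake, pd = pd_list, moa = moa)
}

sample_layout <- function(n = 200, radius = 200)
  list(kind = "disc", n = n, radius = radius, cell_type = "tumor")

#' Configuration of a packaged sample experiment
#'
#' Builds the full, validated configuration for one of the packaged
#' samples (see [list_samples()]): one sample per mechanism of action, a
#' two-drug combination (anti-proliferative + pro-apoptotic), a
#' confluence-triggered dosing start, an SBML-defined PK run whose SBML
#' file is generated on the fly, and two minimal template projects.
#'
#' @param name A sample name from [list_samples()].
#' @param t_end Simulated end time (min); default 2880 (48 h).
#' @param seed RNG seed stored in the config.
#' @return A validated `pkpd_config`.
#' @export
sample_config <- function(name, t_end = 2880, seed = 0L) {
  name <- match.arg(name, SAMPLE_NAMES)
  moa_anti_prolif <- moa_config(prolif = list(
    saturation_rate = 0, EC50 = 100, hill_power = 2))
  moa_pro_apop <- moa_config(apop = list(
    saturation_rate = 2e-3, EC50 = 100, hill_power = 2))
  moa_necrosis <- moa_config(necrosis = list(
    saturation_rate = 2e-3, EC50 = 100, hill_power = 2))
  moa_anti_motility <- moa_config(motility = list(
    saturation_rate = 0.025, EC50 = 100, hill_power = 2))

  build <- function(substrates, tumor, snapshot_interval = 360) {
    validate_config(simulation_config(
      domain = sample_domain(), time = sample_time(t_end),
      substrates = substrates,
      cell_types = list(tumor = tumor),
      initial_cells = sample_layout(),
      pk_substrates = names(substrates),
      pd_substrates = names(substrates),
      seed = seed, snapshot_interval = snapshot_interval))
  }

  switch(name,
    prolif_sample = build(
      list(drugA = sample_pk_entry("drugA")),
      sample_tumor(moa = list(drugA = moa_anti_prolif))),
    apop_sample = build(
      list(drugA = sample_pk_entry("drugA")),
      sample_tumor(moa = list(drugA = moa_pro_apop))),
    necrosis_sample = build(
      list(drugA = sample_pk_entry("drugA")),
      sample_tumor(moa = list(drugA = moa_necrosis))),
    motility_sample = build(
      list(drugA = sample_pk_entry("drugA")),
      sample_tumor(moa = list(drugA = moa_anti_motility))),
    combo_sample = build(
      list(drugP = sample_pk_entry("drugP"),
           drugB = sample_pk_entry("drugB")),
      sample_tumor(moa = list(drugP = moa_anti_prolif,
                              drugB = moa_pro_apop))),
    confluence_start_sample = build(
      list(drugA = sample_pk_entry("drugA", schedule = dose_schedule(
        max_number_doses = 3, dose_interval = 720,
        central_increase_on_dose = 10,
        set_first_dose_time = FALSE, confluence_condition = 0.25))),
      sample_tumor(moa = list(drugA = moa_anti_prolif))),
    sbml_pk_sample = {
      path <- file.path(tempdir(), "pkpdabm_sbml_pk_sample.xml")
      make_toy_sbml("with_events", params = list(
        elimination_rate = 0.01, k12 = 0.005, k21 = 0.005,
        volume_ratio = 1,
        events = data.frame(time = c(0, 720, 1440), amount = 10)),
        path = path)
      substrates <- list(drugA = list(
        diffusion_coefficient = 6e4, decay_rate = 0.01,
        dirichlet_edges = "bottom", pk_model = "SBML",
        biot_number = 1, sbml_file = path))
      build(substrates, sample_tumor(moa = list(drugA = moa_anti_prolif)))
    },
    template_1C = build(
      list(drugA = sample_pk_entry("drugA", model = "1C")),
      sample_tumor(moa = list(drugA = moa_anti_prolif))),
    template_2C = build(
      list(drugA = sample_pk_entry("drugA", model = "2C")),
      sample_tumor(moa = list(drugA = moa_anti_prolif))))
}

#' Run a packaged sample experiment
#'
#' @param name A sample name from [list_samples()].
#' @param seed RNG seed.
#' @param t_end Simulated end time (min).
#' @param output_dir Optional directory for plain-text outputs.
#' @return A `pkpd_run`.
#' @export
run_sample <- function(name, seed = 0L, t_end = 2880, output_dir = NULL) {
  run_simulation(sample_config(name, t_end = t_end, seed = seed),
                 output_dir = output_dir)
}

#' Generate a disc-shaped initial tumor layout
#'
#' Positions are drawn uniformly in a disc centered at the origin and
#' relaxed by the same pairwise repulsion used by the mechanics step
#' until no pair is closer than 1.9 cell radii (cells pushed outside the
#' disc are pulled back to its rim each iteration). Requested densities
#' beyond circle close-packing are an error.
#'
#' @param n_cells Number of cells (>= 0).
#' @param radius_um Disc radius (um).
#' @param cell_type Type name recorded in the layout.
#' @param cell_radius Cell radius (um) used for spacing.
#' @param seed Optional local seed; by default the current RNG stream is
#'   used (so layouts are reproducible under the run seed).
#' @param max_iter Maximum relaxation sweeps.
#' @return A data frame with columns `x`, `y`, `cell_type`.
#' @export
make_initial_tumor <- function(n_cells, radius_um, cell_type = "tumor",
                               cell_radius = 10, seed = NULL,
                               max_iter = 500) {
  stopifnot(n_cells >= 0)
  if (n_cells == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      cell_type = character(0)))
  # hexagonal close packing of circles covers pi/sqrt(12) ~ 0.9069
  if (n_cells * cell_radius^2 > 0.9069 * radius_um^2)
    stop("requested cell density exceeds close packing of the disc")
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  r <- radius_um * sqrt(stats::runif(n_cells))
  th <- stats::runif(n_cells, 0, 2 * pi)
  x <- r * cos(th)
  y <- r * sin(th)
  box <- radius_um + 4 * cell_radius
  target <- 1.9 * cell_radius
  for (it in seq_len(max_iter)) {
    res <- relax_overlaps_cpp(x, y, rep(cell_radius, n_cells), 1, 1,
                              -box, box, -box, box)
    x <- res$x; y <- res$y
    rad <- sqrt(x^2 + y^2)
    out <- rad > radius_um
    if (any(out)) {
      x[out] <- x[out] * radius_um / rad[out]
      y[out] <- y[out] * radius_um / rad[out]
    }
    if (n_cells < 2) break
    dmin <- min(stats::dist(cbind(x, y)))
    if (dmin >= target) break
  }
  data.frame(x = x, y = y, cell_type = cell_type)
}

#' Write a minimal SBML file encoding a linear PK model
#'
#' Generates a valid SBML Level 3 core document with a species named
#' `circulation_concentration` (plus `periphery_concentration` for the
#' two-compartment kind), rate rules encoding the linear kinetics, and
#' optional time-triggered bolus events that increment the circulation.
#' The file round-trips through [load_sbml_pk()].
#'
#' @param kind `"1C"`, `"2C"`, or `"with_events"` (a 2C model plus bolus
#'   events).
#' @param params List with `elimination_rate`, and for the 2C kinds
#'   `k12`, `k21`, `volume_ratio`; `initial` (default 0) sets the initial
#'   circulation concentration; for `"with_events"`, `events` is a data
#'   frame with columns `time` (min) and `amount` (a.u.).
#' @param path Output file path.
#' @param periphery_first If `TRUE`, list the periphery species before
#'   the circulation species (the named-species readout rule must still
#'   find the circulation).
#' @return `path`, invisibly.
#' @export
make_toy_sbml <- function(kind = c("1C", "2C", "with_events"), params,
                          path = tempfile(fileext = ".xml"),
                          periphery_first = FALSE) {
  kind <- match.arg(kind)
  lam <- params$elimination_rate
  init <- params$initial %||% 0
  two <- kind != "1C"
  mathml <- function(inner) paste0(
    '<math xmlns="http://www.w3.org/1998/Math/MathML">', inner, "</math>")
  ci <- function(x) paste0("<ci>", x, "</ci>")
  cn <- function(x) paste0("<cn>", format(x, digits = 17), "</cn>")
  sp <- function(id, v) sprintf(
    '<species id="%s" compartment="central" initialConcentration="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    id, format(v, digits = 17))
  species <- sp("circulation_concentration", init)
  pars <- sprintf('<parameter id="lambda" value="%s" constant="true"/>',
                  format(lam, digits = 17))
  # dC/dt = (k21/R) P - (k12 + lambda) C   |   dC/dt = -lambda C
  rules <- if (two) {
    paste0(
      '<rateRule variable="circulation_concentration">',
      mathml(paste0("<apply><minus/>",
                    "<apply><times/><apply><divide/>", ci("k21"), ci("R"),
                    "</apply>", ci("periphery_concentration"), "</apply>",
                    "<apply><times/><apply><plus/>", ci("k12"), ci("lambda"),
                    "</apply>", ci("circulation_concentration"),
                    "</apply></apply>")),
      "</rateRule>",
      '<rateRule variable="periphery_concentration">',
      mathml(paste0("<apply><minus/>",
                    "<apply><times/>", ci("k12"), ci("R"),
                    ci("circulation_concentration"), "</apply>",
                    "<apply><times/>", ci("k21"),
                    ci("periphery_concentration"), "</apply></apply>")),
      "</rateRule>")
  } else {
    paste0(
      '<rateRule variable="circulation_concentration">',
      mathml(paste0("<apply><minus/><apply><times/>", ci("lambda"),
                    ci("circulation_concentration"), "</apply></apply>")),
      "</rateRule>")
  }
  if (two) {
    psp <- sp("periphery_concentration", 0)
    species <- if (periphery_first) paste0(psp, species)
               else paste0(species, psp)
    pars <- paste0(pars, sprintf(
      '<parameter id="k12" value="%s" constant="true"/><parameter id="k21" value="%s" constant="true"/><parameter id="R" value="%s" constant="true"/>',
      format(params$k12, digits = 17), format(params$k21, digits = 17),
      format(params$volume_ratio, digits = 17)))
  }
  events <- ""
  if (kind == "with_events") {
    ev <- params$events
    time_sym <- '<csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time"> t </csymbol>'
    events <- paste0(
      "<listOfEvents>",
      paste0(vapply(seq_len(nrow(ev)), function(i) paste0(
        sprintf('<event id="dose%d" useValuesFromTriggerTime="true">', i),
        "<trigger initialValue=\"false\" persistent=\"true\">",
        mathml(paste0("<apply><geq/>", time_sym, cn(ev$time[i]), "</apply>")),
        "</trigger><listOfEventAssignments>",
        '<eventAssignment variable="circulation_concentration">',
        mathml(paste0("<apply><plus/>", ci("circulation_concentration"),
                      cn(ev$amount[i]), "</apply>")),
        "</eventAssignment></listOfEventAssignments></event>"), ""),
      collapse = ""),
      "</listOfEvents>")
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
    '<model id="toy_pk" name="toy linear PK model">\n',
    '<listOfCompartments><compartment id="central" size="1" constant="true"/></listOfCompartments>\n',
    "<listOfSpecies>", species, "</listOfSpecies>\n",
    "<listOfParameters>", pars, "</listOfParameters>\n",
    "<listOfRules>", rules, "</listOfRules>\n",
    events, "\n</model>\n</sbml>\n")
  writeLines(doc, path)
  invisible(path)
}

#' Dose sweep for an IC50-style response curve
#'
#' Replicates the single-dose response experiment: for each dose
#' (including a zero-dose control) the base configuration is modified so
#' exactly one bolus of that amount is given at t = 0, run to `t_end`
#' over `replicates` seeds, and the final cell count is reported relative
#' to the mean control count. The control's mean relative size is 1 by
#' construction.
#'
#' @param base_config A `pkpd_config` with at least one anti-proliferative
#'   MOA configured (the sample to sweep; see [sample_config()]).
#' @param doses Numeric vector of bolus amounts (a.u.); 0 is added if
#'   absent. Defaults to a control plus 7 doses log-spaced over 3.5
#'   orders of magnitude.
#' @param replicates Seeds per dose (> 0).
#' @param seed Base seed; run r of dose i uses
#'   `seed + (i - 1) * replicates + (r - 1)`.
#' @param t_end Simulated end time (min), default 2880 (48 h).
#' @return An object of class `dose_sweep`: a list with `results` (one
#'   row per run: dose, replicate, seed, final_count, relative_size) and
#'   `summary` (per dose: mean and SD of relative size).
#' @export
run_ic50_sweep <- function(base_config,
                           doses = c(0, 10^seq(-1.5, 2, length.out = 7)),
                           replicates = 5, seed = 0L, t_end = 2880) {
  if (replicates < 1) stop("replicates must be >= 1")
  base_config <- validate_config(base_config)
  has_prolif <- any(vapply(base_config$cell_types, function(t)
    any(vapply(t$moa, function(m) "prolif" %in% names(m), TRUE)), TRUE))
  if (!has_prolif)
    stop("base config has no anti-proliferative MOA to sweep")
  pk_sub <- base_config$pk_substrates[[1L]]
  if (!0 %in% doses) doses <- c(0, doses)
  doses <- sort(doses)
  base_config$time$t_end <- t_end
  base_config$snapshot_interval <- Inf
  rows <- list()
  for (i in seq_along(doses)) {
    d <- doses[[i]]
    cfg <- base_config
    cfg$substrates[[pk_sub]]$schedule <- if (d > 0)
      dose_schedule(max_number_doses = 1, central_increase_on_dose = d,
                    set_first_dose_time = TRUE, first_dose_time = 0)
      else dose_schedule(max_number_doses = 0)
    for (r in seq_len(replicates)) {
      run_seed <- seed + (i - 1L) * replicates + (r - 1L)
      run <- run_simulation(cfg, seed = run_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dose = d, replicate = r, seed = run_seed,
        final_count = ncells(run$cells))
    }
  }
  results <- do.call(rbind, rows)
  control_mean <- mean(results$final_count[results$dose == 0])
  results$relative_size <- results$final_count / control_mean
  agg_m <- stats::aggregate(relative_size ~ dose, results, mean)
  agg_s <- stats::aggregate(relative_size ~ dose, results, stats::sd)
  summary <- data.frame(dose = agg_m$dose,
                        mean_relative = agg_m$relative_size,
                        sd_relative = agg_s$relative_size)
  structure(list(results = results, summary = summary),
            class = "dose_sweep")
}

#' @export
print.dose_sweep <- function(x, ...) {
  cat("dose_sweep:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
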