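# Configuration policy and the coupled simulation loop.

minimal_yaml <- function(extra_substrate = "", extra_custom = "",
                         pk_model_line = "    drugA_pk_model: 1C\n",
                         biot_line = "    drugA_biot_number: 1\n") {
  paste0(
    "domain: {x_min: -200, x_max: 200, y_min: -200, y_max: 200, voxel_size: 20}\n",
    "time: {diffusion_dt: 0.1, mechanics_dt: 1, phenotype_dt: 6, t_end: 60}\n",
    "seed: 1\n",
    "output: {snapshot_interval: 60}\n",
    "user_parameters:\n",
    "  PKPD_pk_substrate_names: drugA\n",
    "  PKPD_pd_substrate_names: drugA\n",
    "substrates:\n",
    "  drugA:\n",
    "    diffusion_coefficient: 60000\n",
    "    decay_rate: 0.01\n",
    "    dirichlet_edges: bottom\n",
    pk_model_line, biot_line,
    "    drugA_central_elimination_rate: 0.01\n",
    "    drugA_max_number_doses: 1\n",
    "    drugA_central_increase_on_dose: 10\n",
    "    drugA_set_first_dose_time: true\n",
    "    drugA_first_dose_time: 0\n",
    extra_substrate,
    "cell_types:\n",
    "  tumor:\n",
    "    radius: 10\n",
    "    prolif_rate: 0.0005\n",
    "    uptake: {drugA: 0.02}\n",
    "    custom_data:\n",
    "      drugA_on_tumor_pd_model: AUC\n",
    "      drugA_metabolism_rate: 0.05\n",
    "      drugA_repair_rate_constant: 0.0001\n",
    "      drugA_repair_rate_linear: 0.005\n",
    "      drugA_moa_is_prolif: 1\n",
    "      drugA_prolif_saturation_rate: 0\n",
    "      drugA_prolif_EC50: 100\n",
    "      drugA_prolif_hill_power: 2\n",
    extra_custom,
    "initial_cells: {kind: disc, n: 20, radius: 100, cell_type: tumor}\n")
}

write_yaml_config <- function(txt) {
  path <- tempfile(fileext = ".yaml")
  writeLines(txt, path)
  path
}

test_that("a fully specified YAML config loads without warnings", {
  cfg <- expect_silent(load_config(write_yaml_config(minimal_yaml())))
  expect_s3_class(cfg, "pkpd_config")
  expect_equal(cfg$substrates$drugA$pk_model, "1C")
  expect_equal(cfg$substrates$drugA$biot_number, 1)
  expect_length(cfg$load_log, 0)
})

test_that("missing PK model and Biot number default with one warning each", {
  path <- write_yaml_config(minimal_yaml(pk_model_line = "", biot_line = ""))
  warns <- capture_warnings(cfg <- load_config(path))
  expect_length(grep("pk_model missing.*two-compartment", warns), 1)
  expect_length(grep("biot_number missing", warns), 1)
  expect_equal(cfg$substrates$drugA$pk_model, "2C")
  expect_s3_class(cfg$substrates$drugA$pk_params, "pk_2c_params")
  expect_equal(cfg$substrates$drugA$biot_number, 1)
})

test_that("a sub-threshold MOA flag leaves the MOA inactive", {
  txt <- minimal_yaml()
  txt <- sub("drugA_moa_is_prolif: 1", "drugA_moa_is_prolif: 0.4", txt)
  cfg <- suppressWarnings(load_config(write_yaml_config(txt)))
  expect_null(cfg$cell_types$tumor$moa$drugA)
})

test_that("every hard configuration error is reported at once", {
  txt <- minimal_yaml()
  txt <- sub("    drugA_central_increase_on_dose: 10\n", "", txt)
  txt <- sub("      drugA_metabolism_rate: 0.05\n", "", txt)
  err <- tryCatch(load_config(write_yaml_config(txt)), error = function(e)
    conditionMessage(e))
  expect_match(err, "drugA_central_increase_on_dose is required")
  expect_match(err, "drugA_metabolism_rate is required")
})

test_that("cross-reference and EC50 validation reject broken configs", {
  txt <- minimal_yaml()
  txt <- sub("PKPD_pd_substrate_names: drugA", "PKPD_pd_substrate_names: ghost",
             txt)
  expect_error(suppressWarnings(load_config(write_yaml_config(txt))),
               "ghost")
  txt2 <- sub("drugA_prolif_EC50: 100", "drugA_prolif_EC50: -1",
              minimal_yaml())
  expect_error(load_config(write_yaml_config(txt2)), "EC50")
  txt3 <- sub("drugA_pk_model: 1C", "drugA_pk_model: 3C", minimal_yaml())
  expect_error(load_config(write_yaml_config(txt3)), "unknown pk model")
})

test_that("a null simulation returns the input layout unchanged", {
  layout <- data.frame(x = c(-50, 0, 50), y = c(0, 30, -30),
                       cell_type = "inert")
  cfg <- simulation_config(
    domain = list(x_min = -200, x_max = 200, y_min = -200, y_max = 200,
                  voxel_size = 20),
    time = list(diffusion_dt = 0.1, mechanics_dt = 1, phenotype_dt = 6,
                t_end = 60),
    substrates = list(), cell_types = list(inert = cell_type("inert")),
    initial_cells = layout, seed = 3, snapshot_interval = Inf)
  run <- run_simulation(cfg)
  expect_equal(run$cells$x, layout$x)
  expect_equal(run$cells$y, layout$y)
  expect_equal(ncells(run$cells), 3)
})

test_that("doses at a step boundary are applied before the PK advance", {
  cfg <- suppressWarnings(load_config(write_yaml_config(minimal_yaml())))
  cfg$initial_cells <- NULL
  run <- run_simulation(cfg, seed = 1)
  pk1 <- run$pk_trajectory[run$pk_trajectory$time_min == 1, ]
  # dose of 10 at t = 0 enters before the first 0.1 min interval:
  # C(1 min) = 10 exp(-lambda * 1)
  expect_equal(pk1$circulation, 10 * exp(-0.01), tolerance = 1e-12)
})

test_that("with no cells the field approaches the PK-scaled boundary profile", {
  # slow elimination: the field tracks the quasi-static Dirichlet value
  cfg <- suppressWarnings(load_config(write_yaml_config(minimal_yaml())))
  cfg$initial_cells <- NULL
  cfg$substrates$drugA$pk_params <- one_compartment_params(1e-5)
  cfg$time$t_end <- 360
  run <- run_simulation(cfg, seed = 1)
  u <- run$grid$substrates$drugA$u
  C <- run$pk_trajectory$circulation[nrow(run$pk_trajectory)]
  # with decay length sqrt(D/decay) ~ 2.4 mm >> 0.4 mm domain the
  # steady field is within a few percent of the boundary value
  expect_gt(min(u) / C, 0.9)
  expect_equal(max(u), C, tolerance = 1e-6)
})

test_that("PD bookkeeping without MOAs leaves population dynamics untouched", {
  txt <- minimal_yaml()
  for (key in c("      drugA_moa_is_prolif: 1\n",
                "      drugA_prolif_saturation_rate: 0\n",
                "      drugA_prolif_EC50: 100\n",
                "      drugA_prolif_hill_power: 2\n"))
    txt <- sub(key, "", txt)
  cfg_no_moa <- suppressWarnings(load_config(write_yaml_config(txt)))
  cfg_no_drug <- cfg_no_moa
  cfg_no_drug$substrates$drugA$schedule <- dose_schedule(max_number_doses = 0)
  cfg_no_moa$time$t_end <- cfg_no_drug$time$t_end <- 360
  a <- run_simulation(cfg_no_moa, seed = 12)
  b <- run_simulation(cfg_no_drug, seed = 12)
  expect_identical(a$cells$x, b$cells$x)
  expect_identical(a$cells$id, b$cells$id)
  expect_gt(max(a$cells$D[, "drugA"]), 0) # damage accrued, but inert
})

test_that("run summaries handle zero and positive damage correctly", {
  fake <- structure(list(
    config = list(cell_types = list(tumor = NULL), pd_substrates = "drugA"),
    snapshots = list(
      list(time = 0, cells = data.frame(type = "tumor", D_drugA = 0)),
      list(time = 6, cells = data.frame(type = "tumor", D_drugA = 100)))),
    class = "pkpd_run")
  s <- summarize_run(fake)
  expect_true(is.na(s$mean_log10_damage_drugA[1]))
  expect_false(is.infinite(s$mean_log10_damage_drugA[1] %||% Inf))
  expect_equal(s$mean_log10_damage_drugA[2], 2)
  expect_equal(s$sd_log10_damage_drugA[2], 0)
})
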