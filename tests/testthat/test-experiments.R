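# Sample experiments, fixture generators, and the dose-sweep harness.

test_that("disc layouts are contained, well separated, and density-checked", {
  expect_equal(nrow(make_initial_tumor(0, 100)), 0)
  lay <- make_initial_tumor(150, 200, cell_radius = 10, seed = 4)
  expect_true(all(sqrt(lay$x^2 + lay$y^2) <= 200 + 1e-9))
  expect_gte(min(stats::dist(cbind(lay$x, lay$y))), 1.9 * 10)
  expect_error(make_initial_tumor(500, 100, cell_radius = 10),
               "close packing")
})

test_that("every packaged sample config validates and the registry is complete", {
  expect_setequal(list_samples(),
                  c("prolif_sample", "apop_sample", "necrosis_sample",
                    "motility_sample", "combo_sample",
                    "confluence_start_sample", "sbml_pk_sample",
                    "template_1C", "template_2C"))
  for (nm in list_samples()) {
    cfg <- sample_config(nm, t_end = 60)
    expect_s3_class(cfg, "pkpd_config")
    expect_true(cfg$validated)
  }
})

test_that("the anti-proliferative drug lowers final counts on paired seeds", {
  seeds <- 1:3
  on_off <- vapply(seeds, function(s) {
    cfg_on <- sample_config("prolif_sample", t_end = 1080, seed = s)
    cfg_off <- cfg_on
    cfg_off$substrates$drugA$schedule <- dose_schedule(max_number_doses = 0)
    c(ncells(run_simulation(cfg_on)$cells),
      ncells(run_simulation(cfg_off)$cells))
  }, c(on = 0, off = 0))
  expect_true(all(on_off["on", ] < on_off["off", ]))
})

test_that("the pro-apoptotic drug produces death events well above the base expectation", {
  run <- run_sample("apop_sample", seed = 2, t_end = 1440)
  # base apoptosis alone: ~200 cells * 5e-5/min * 1440 min ~ 14 deaths
  expect_gt(run$events$n_apoptosis, 40)
  cfg_off <- sample_config("apop_sample", t_end = 1440, seed = 2)
  cfg_off$substrates$drugA$schedule <- dose_schedule(max_number_doses = 0)
  run_off <- run_simulation(cfg_off)
  expect_gt(run$events$n_apoptosis, 2 * run_off$events$n_apoptosis)
})

test_that("the necrosis drug kills despite a zero base necrosis rate", {
  run <- run_sample("necrosis_sample", seed = 2, t_end = 1440)
  expect_gt(run$events$n_necrosis, 0)
  cfg_off <- sample_config("necrosis_sample", t_end = 1440, seed = 2)
  cfg_off$substrates$drugA$schedule <- dose_schedule(max_number_doses = 0)
  expect_equal(run_simulation(cfg_off)$events$n_necrosis, 0)
})

test_that("the anti-motility drug reduces cell displacement on paired seeds", {
  disp <- function(with_drug, s) {
    cfg <- sample_config("motility_sample", t_end = 720, seed = s)
    # freeze division/death so displacement is per-cell comparable
    cfg$cell_types$tumor$prolif_rate <- 0
    cfg$cell_types$tumor$apop_rate <- 0
    if (!with_drug)
      cfg$substrates$drugA$schedule <- dose_schedule(max_number_doses = 0)
    run <- run_simulation(cfg)
    start <- run$snapshots[[1]]$cells
    end <- run$snapshots[[length(run$snapshots)]]$cells
    m <- merge(start, end, by = "id")
    mean(sqrt((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2))
  }
  for (s in 1:2) expect_lt(disp(TRUE, s), disp(FALSE, s))
})

test_that("combination therapy is at least as effective as either single drug", {
  final_count <- function(name, s) {
    ncells(run_simulation(sample_config(name, t_end = 1440, seed = s))$cells)
  }
  for (s in 1:2) {
    combo <- final_count("combo_sample", s)
    single <- min(final_count("prolif_sample", s),
                  final_count("apop_sample", s))
    expect_lte(combo, single * 1.1) # independent action, noise allowance
  }
})

test_that("confluence-triggered dosing starts at the first monitored crossing", {
  cfg <- sample_config("confluence_start_sample", t_end = 1080, seed = 5)
  cfg$substrates$drugA$schedule <- dose_schedule(
    max_number_doses = 2, dose_interval = 720,
    central_increase_on_dose = 10,
    set_first_dose_time = FALSE, confluence_condition = 0.12)
  run <- run_simulation(cfg)
  expect_gt(nrow(run$doses), 0)
  crossing <- run$confluence$time[run$confluence$confluence >= 0.12][1]
  expect_equal(run$doses$time_min[1], crossing)
  before <- run$confluence[run$confluence$time < crossing, ]
  expect_true(all(before$confluence < 0.12))
})

test_that("toy SBML fixtures encode the requested bolus content", {
  path <- make_toy_sbml("with_events", list(
    elimination_rate = 0, k12 = 0, k21 = 0, volume_ratio = 1,
    events = data.frame(time = 60, amount = 10)))
  m <- load_sbml_pk(path)
  expect_length(m$events, 1)
  expect_equal(m$events[[1]]$time, 60)
  before <- simulate_sbml_pk(m, c(0, 59.9))$circulation[2]
  after <- simulate_sbml_pk(load_sbml_pk(path), c(0, 60.1))$circulation[2]
  expect_equal(after - before, 10, tolerance = 1e-8)
})

test_that("the packaged YAML sample is equivalent to the programmatic configuration", {
  path <- system.file("extdata", "prolif_sample.yaml", package = "pkpdabm")
  cfg <- expect_silent(load_config(path))
  ref <- sample_config("prolif_sample")
  expect_equal(cfg$substrates$drugA$pk_params, ref$substrates$drugA$pk_params)
  expect_equal(cfg$substrates$drugA$schedule, ref$substrates$drugA$schedule)
  expect_equal(cfg$cell_types$tumor$pd$drugA, ref$cell_types$tumor$pd$drugA)
  expect_equal(cfg$cell_types$tumor$moa$drugA, ref$cell_types$tumor$moa$drugA)
  expect_equal(cfg$cell_types$tumor$uptake, ref$cell_types$tumor$uptake)
})

test_that("the dose sweep validates its inputs", {
  cfg <- sample_config("prolif_sample", t_end = 60)
  expect_error(run_ic50_sweep(cfg, replicates = 0), "replicates")
  cfg_no <- sample_config("necrosis_sample", t_end = 60)
  expect_error(run_ic50_sweep(cfg_no, replicates = 1),
               "anti-proliferative")
})
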