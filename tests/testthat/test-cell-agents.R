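# Off-lattice population: division/death sampling, mechanics,
# confluence, coloring, and determinism.

test_that("a population with all rates zero is inert", {
  cells <- make_test_population(6)
  set.seed(1)
  res <- phenotype_step(cells, 6, test_domain())
  expect_equal(ncells(res$cells), 6)
  expect_equal(res$events$n_division + res$events$n_apoptosis +
                 res$events$n_necrosis, 0)
  expect_identical(res$cells$x, cells$x)

  set.seed(1)
  moved <- mechanics_step(cells, 1, test_domain())
  expect_identical(moved$x, cells$x) # speed 0, no overlaps
})

test_that("division frequency matches the exponential-waiting-time model", {
  n <- 1e4
  types <- list(t = cell_type("t", radius = 5, prolif_rate = 0.001))
  cells <- cell_population(x = runif(n, -390, 390), y = runif(n, -390, 390),
                           type = "t", types = types)
  set.seed(42)
  res <- phenotype_step(cells, 6, test_domain())
  frac <- res$events$n_division / n
  p <- 1 - exp(-0.001 * 6)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("dominant apoptosis shrinks the population in expectation", {
  types <- list(t = cell_type("t", radius = 5, prolif_rate = 1e-4,
                              apop_rate = 5e-3))
  signs <- vapply(1:8, function(s) {
    set.seed(s)
    cells <- cell_population(x = runif(200, -300, 300),
                             y = runif(200, -300, 300),
                             type = "t", types = types)
    for (i in 1:10) cells <- phenotype_step(cells, 6, test_domain())$cells
    ncells(cells) < 200
  }, TRUE)
  expect_true(all(signs))
})

test_that("overlapping cells are pushed apart and lone walkers diffuse", {
  types <- list(t = cell_type("t", radius = 10))
  cells <- cell_population(x = c(0, 10), y = c(0, 0), type = "t",
                           types = types)
  set.seed(5)
  moved <- mechanics_step(cells, 0.1, test_domain())
  d0 <- 10
  d1 <- abs(diff(moved$x))
  expect_gt(sqrt(d1^2 + diff(moved$y)^2), d0)

  # mean-squared displacement of a persistent walker grows ~ linearly
  types2 <- list(t = cell_type("t", radius = 5, motility_speed = 1,
                               persistence_time = 5))
  msd_at <- function(n_steps) {
    mean(vapply(1:40, function(s) {
      set.seed(s)
      cells <- cell_population(x = 0, y = 0, type = "t", types = types2)
      for (i in seq_len(n_steps))
        cells <- mechanics_step(cells, 1, list(x_min = -1e4, x_max = 1e4,
                                               y_min = -1e4, y_max = 1e4))
      cells$x^2 + cells$y^2
    }, 0))
  }
  m200 <- msd_at(200)
  m400 <- msd_at(400)
  expect_gt(m400 / m200, 1.5) # linear growth, not saturation
  expect_lt(m400 / m200, 2.8) # and not ballistic
})

test_that("confluence is the capped summed footprint over the domain area", {
  dom <- test_domain()
  types <- list(t = cell_type("t", radius = 10))
  none <- cell_population(types = types)
  expect_equal(confluence(none, dom), 0)
  one <- cell_population(x = 0, y = 0, type = "t", types = types)
  expect_equal(confluence(one, dom), pi * 100 / 640000)
  crowd <- cell_population(x = rep(0, 3000), y = rep(0, 3000), type = "t",
                           types = types)
  expect_equal(confluence(crowd, dom), 1)
})

test_that("damage coloring is deterministic, anchored, and monotone per channel", {
  base <- damage_coloring(0, 10, 0, 10)
  expect_equal(unname(base[1, ]), c(0.8, 0.8, 0.8))
  sat <- damage_coloring(1e9, 10, 1e9, 10)
  expect_equal(unname(sat[1, ]), c(0.35, 0, 0.35), tolerance = 1e-6)
  ladder <- damage_coloring(c(0, 5, 10, 100, 1e4), 10)
  expect_true(all(diff(ladder[, "r"]) > 0 | abs(diff(ladder[, "r"])) < 1e-12))
  expect_true(all(diff(ladder[, "g"]) < 0))
  expect_identical(damage_coloring(3, 7, 2, 9), damage_coloring(3, 7, 2, 9))
})

test_that("rates revert to base exactly when damage is zero", {
  moa <- suppressWarnings(moa_config(prolif = list(saturation_rate = 0,
                                                   EC50 = 10, hill_power = 1)))
  types <- list(t = cell_type("t", radius = 5, prolif_rate = 1e-3,
                              pd = list(drug = pd_params(0.1, 0, 0.01, dt = 1)),
                              moa = list(drug = moa)))
  cells <- cell_population(x = c(0, 50), y = c(0, 0), type = "t",
                           types = types, pd_substrates = "drug")
  cells$D[, "drug"] <- c(5, 0)
  cells <- pkpdabm:::apply_moas_population(cells)
  expect_lt(cells$rate_prolif[1], 1e-3)
  expect_identical(cells$rate_prolif[2], 1e-3)
  cells$D[, "drug"] <- 0
  cells <- pkpdabm:::apply_moas_population(cells)
  expect_identical(cells$rate_prolif, c(1e-3, 1e-3))
})

test_that("division splits amount-based pools and copies concentration-based ones", {
  mk <- function(model) {
    types <- list(t = cell_type("t", radius = 5, prolif_rate = 100,
                                pd = list(drug = pd_params(0, 0, 0, dt = 1,
                                                           damage_model = model))))
    cells <- cell_population(x = 0, y = 0, type = "t", types = types,
                             pd_substrates = "drug")
    cells$A[, "drug"] <- 8
    cells$D[, "drug"] <- 4
    set.seed(2)
    phenotype_step(cells, 6, test_domain())$cells
  }
  amt <- mk("AUC_amount")
  expect_equal(ncells(amt), 2)
  expect_equal(unname(amt$A[, "drug"]), c(4, 4))
  expect_equal(unname(amt$D[, "drug"]), c(2, 2))
  conc <- mk("AUC")
  expect_equal(unname(conc$A[, "drug"]), c(8, 8))
  expect_equal(unname(conc$D[, "drug"]), c(4, 4))
})

test_that("identical seeds give bit-identical trajectories", {
  roll <- function() {
    set.seed(99)
    types <- list(t = cell_type("t", radius = 8, prolif_rate = 5e-4,
                                apop_rate = 1e-4, motility_speed = 0.5))
    cells <- cell_population(x = runif(50, -100, 100),
                             y = runif(50, -100, 100),
                             type = "t", types = types)
    for (i in 1:30) {
      cells <- mechanics_step(cells, 1, test_domain())
      if (i %% 6 == 0) cells <- phenotype_step(cells, 6, test_domain())$cells
    }
    cells
  }
  a <- roll()
  b <- roll()
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$id, b$id)
})
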