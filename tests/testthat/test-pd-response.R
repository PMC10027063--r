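# Damage dynamics, precomputation, Hill factors, and MOA combination.

test_that("the closed-form damage update matches the ODE oracle on all branches", {
  # origin with no constant repair is a fixed point
  z <- pd_step(list(A = 0, D = 0),
               pd_params(0.02, 0, 0.01, dt = 1))
  expect_identical(z$A, 0)
  expect_identical(z$D, 0)

  cases <- expand.grid(m = c(0, 0.02, 0.05), r1 = c(0, 0.01, 0.05),
                       r0 = c(0, 0.005), dt = c(0.1, 1, 6))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- pd_step(list(A = 1, D = 0.4),
                   pd_params(cs$m, cs$r0, cs$r1, dt = cs$dt))
    want <- oracle_pd(1, 0.4, cs$m, cs$r0, cs$r1, cs$dt)
    expect_lt(rel_err(got$A, want[1]), 1e-9)
    if (want[2] > 0) expect_lt(rel_err(got$D, want[2]), 1e-9)
    else expect_identical(got$D, 0)
  }
})

test_that("the repeated-rate branch m = r1 is the continuous limit of its neighbourhood", {
  base <- pd_step(list(A = 2, D = 1), pd_params(0.05, 0.001, 0.05, dt = 6))
  for (eps in c(1e-7, 1e-9)) {
    near <- pd_step(list(A = 2, D = 1),
                    pd_params(0.05 + eps, 0.001, 0.05 - eps, dt = 6))
    expect_lt(rel_err(near$D, base$D), 1e-6)
  }
  want <- oracle_pd(2, 1, 0.05, 0.001, 0.05, 6)
  expect_lt(rel_err(base$D, want[2]), 1e-9)
})

test_that("damage is clamped at zero where constant repair overshoots", {
  got <- pd_step(list(A = 0, D = 0.001), pd_params(0, 1, 0, dt = 1))
  expect_identical(got$D, 0)
  raw <- oracle_pd(0, 0.001, 0, 1, 0, 1)
  expect_lt(raw[2], 0)
})

test_that("precomputed constants are bit-identical to direct evaluation and stay coherent", {
  p <- pd_params(0.03, 2e-4, 0.008, dt = 0.5)
  pre <- pd_constants(p)
  set.seed(11)
  A <- runif(1e4, 0, 50)
  D <- runif(1e4, 0, 500)
  direct <- pd_step(list(A = A, D = D), p)
  cached <- pd_step(list(A = A, D = D), pre)
  expect_identical(direct$A, cached$A)
  expect_identical(direct$D, cached$D)

  # changing the step invalidates and rebuilds the constants
  stale <- pd_refresh(pre, p, dt = 2)
  expect_false(identical(stale$transfer, pre$transfer))
  expect_identical(pd_step(list(A = A, D = D), stale)$D,
                   pd_step(list(A = A, D = D), pd_params(0.03, 2e-4, 0.008,
                                                         dt = 2))$D)
  expect_identical(pd_refresh(pre, p), pre)

  # heterogeneous parameters with the cache bypassed: per-cell direct
  p2 <- pd_params(0.07, 1e-4, 0.004, dt = 0.5, precompute = FALSE)
  mix <- mapply(function(a, d, use2) {
    prm <- if (use2) p2 else p
    pd_step(list(A = a, D = d), prm)$D
  }, A[1:100], D[1:100], rep(c(TRUE, FALSE), 50))
  ref <- ifelse(rep(c(TRUE, FALSE), 50),
                pd_step(list(A = A[1:100], D = D[1:100]), p2)$D,
                pd_step(list(A = A[1:100], D = D[1:100]), p)$D)
  expect_identical(unname(mix), ref)
})

test_that("with constant drive the damage approaches its analytic equilibrium", {
  # m = 0 keeps A fixed; D -> (A - r0)/r1
  p <- pd_params(0, 0.2, 0.01, dt = 1)
  st <- list(A = 1, D = 0)
  steps <- ceiling(20 / 0.01) # 20 time constants
  pre <- pd_constants(p)
  for (i in seq_len(steps)) st <- pd_step(st, pre)
  expect_equal(st$D, (1 - 0.2) / 0.01, tolerance = 1e-3)
})

test_that("the Hill factor has the pinned values, bounds, and monotonicity", {
  expect_identical(hill_factor(0, EC50 = 10, n = 2, f_sat = 0.2), 1)
  expect_equal(hill_factor(10, 10, 2, 0.2), (1 + 0.2) / 2)
  expect_equal(hill_factor(10, 10, 3.7, 5), (1 + 5) / 2)
  expect_equal(hill_factor(1e6 * 10, 10, 2, 5), 5, tolerance = 1e-9)

  D <- seq(0, 1000, by = 5)
  up <- hill_factor(D, 50, 1.5, 4)
  dn <- hill_factor(D, 50, 1.5, 0.1)
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(dn) <= 0))
  expect_true(all(up >= 1 & up <= 4))
  expect_true(all(dn <= 1 & dn >= 0.1))
  expect_error(hill_factor(1, EC50 = 0, n = 1, f_sat = 1), "EC50")
})

test_that("MOA application resets to base, multiplies factors, and adds necrosis effects", {
  cell <- list(base_rates = list(prolif = 0.001, apop = 1e-4,
                                 necrosis = 0, motility = 0.5),
               rates = list(prolif = 99, apop = 99, necrosis = 99,
                            motility = 99))
  # no MOAs: rates reset to base exactly
  out <- apply_moas(cell)
  expect_identical(out$rates, cell$base_rates)

  moa1 <- suppressWarnings(moa_config(prolif = list(
    saturation_rate = 0, EC50 = 10, hill_power = 1)))
  moa2 <- suppressWarnings(moa_config(prolif = list(
    saturation_rate = 2e-4, EC50 = 20, hill_power = 2)))
  act <- list(list(moa = moa1, state = list(D = 10)),
              list(moa = moa2, state = list(D = 20)))
  out2 <- apply_moas(cell, act)
  f1 <- hill_factor(10, 10, 1, 0 / 0.001)
  f2 <- hill_factor(20, 20, 2, 2e-4 / 0.001)
  expect_equal(out2$rates$prolif, 0.001 * f1 * f2)

  # order independence and idempotence
  out3 <- apply_moas(apply_moas(cell, rev(act)), act)
  expect_equal(out3$rates, out2$rates)

  # additive necrosis: half the saturation rate at D = EC50
  moaN <- moa_config(necrosis = list(saturation_rate = 0.01, EC50 = 5,
                                     hill_power = 1))
  outN <- apply_moas(cell, list(list(moa = moaN, state = list(D = 5))))
  expect_equal(outN$rates$necrosis, 0.005)
  moaN2 <- moa_config(necrosis = list(saturation_rate = 0.004, EC50 = 5,
                                      hill_power = 1))
  outN2 <- apply_moas(cell, list(list(moa = moaN, state = list(D = 5)),
                                 list(moa = moaN2, state = list(D = 5))))
  expect_equal(outN2$rates$necrosis, 0.005 + 0.002)

  # multiplicative MOA on a zero base rate is a configuration error
  cell0 <- list(base_rates = list(prolif = 0, apop = 0, necrosis = 0,
                                  motility = 0), rates = list())
  expect_error(apply_moas(cell0, list(list(moa = moa1, state = list(D = 1)))),
               "base rate 0")
})

test_that("MOA configuration validates its parameters", {
  expect_error(moa_config(prolif = list(EC50 = 1)), "saturation_rate")
  expect_error(moa_config(apop = list(saturation_rate = 1, EC50 = -2)),
               "EC50")
  expect_warning(m <- moa_config(apop = list(saturation_rate = 1, EC50 = 2)),
                 "hill_power")
  expect_equal(m$apop$hill_power, 1)
})
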