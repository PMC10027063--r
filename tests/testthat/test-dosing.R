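# Dose schedule algebra: event enumeration, loading doses, truncation,
# and the confluence trigger.

test_that("dose event enumeration matches the definition on pinned cases", {
  none <- dose_schedule(max_number_doses = 0)
  expect_equal(nrow(build_dose_times(none, 0, 1e6)), 0)

  sch <- dose_schedule(max_number_doses = 4, number_loading_doses = 2,
                       dose_interval = 60, central_increase_on_dose = 10,
                       central_increase_on_loading_dose = 20)
  ev <- build_dose_times(sch, 0, Inf)
  expect_equal(ev$time, c(0, 60, 120, 180))
  expect_equal(ev$amount, c(20, 20, 10, 10))
  expect_equal(ev$is_loading, c(TRUE, TRUE, FALSE, FALSE))

  sch2 <- dose_schedule(max_number_doses = 5, dose_interval = 60,
                        central_increase_on_dose = 1)
  ev2 <- build_dose_times(sch2, 0, 130)
  expect_equal(ev2$time, c(0, 60, 120))
})

test_that("event lists agree with a brute-force enumerator over randomized schedules", {
  set.seed(7)
  for (i in 1:50) {
    maxd <- sample(0:8, 1)
    nload <- if (maxd > 0) sample(0:maxd, 1) else 0
    sch <- suppressWarnings(dose_schedule(
      max_number_doses = maxd,
      number_loading_doses = nload,
      dose_interval = if (maxd > 1) runif(1, 10, 600) else NULL,
      central_increase_on_dose = if (maxd > 0) runif(1, 0, 50) else NULL,
      central_increase_on_loading_dose =
        if (nload > 0) runif(1, 0, 100) else NULL))
    start <- runif(1, 0, 500)
    t_end <- runif(1, 0, 3000)
    got <- build_dose_times(sch, start, t_end)
    want <- brute_force_doses(sch, start, t_end)
    expect_equal(got$time, want$time)
    expect_equal(got$amount, want$amount)
    expect_equal(got$is_loading, want$is_loading)
    # invariants: count cap, loading precede maintenance, total amount
    expect_lte(nrow(got), sch$max_number_doses)
    if (any(got$is_loading) && any(!got$is_loading))
      expect_lt(max(got$time[got$is_loading]), min(got$time[!got$is_loading]))
    n_l <- sum(got$is_loading)
    expect_equal(sum(got$amount),
                 n_l * (sch$central_increase_on_loading_dose %||%
                          sch$central_increase_on_dose %||% 0) +
                   (nrow(got) - n_l) * (sch$central_increase_on_dose %||% 0))
  }
})

test_that("first dose time is the fixed time or the first monitored crossing", {
  fixed <- dose_schedule(max_number_doses = 1, central_increase_on_dose = 1,
                         set_first_dose_time = TRUE, first_dose_time = 180)
  expect_equal(resolve_first_dose_time(fixed), 180)

  conf <- dose_schedule(max_number_doses = 1, central_increase_on_dose = 1,
                        set_first_dose_time = FALSE,
                        confluence_condition = 0.6)
  series <- data.frame(time = seq(0, 600, by = 6),
                       confluence = seq(0, 1, length.out = 101))
  # crossing happens between checks; the first check at/after it wins
  expect_equal(resolve_first_dose_time(conf, series),
               series$time[which(series$confluence >= 0.6)[1]])

  zero <- dose_schedule(max_number_doses = 1, central_increase_on_dose = 1,
                        set_first_dose_time = FALSE,
                        confluence_condition = 0)
  expect_equal(resolve_first_dose_time(zero, series), 0)

  never <- dose_schedule(max_number_doses = 1, central_increase_on_dose = 1,
                         set_first_dose_time = FALSE,
                         confluence_condition = 0.99)
  short <- data.frame(time = c(0, 6), confluence = c(0.1, 0.2))
  expect_warning(t1 <- resolve_first_dose_time(never, short),
                 "never reached")
  expect_true(is.na(t1))
})

test_that("schedule construction enforces the missing-parameter policy", {
  expect_error(dose_schedule(max_number_doses = 2, dose_interval = NULL,
                             central_increase_on_dose = 1),
               "dose_interval")
  expect_error(dose_schedule(max_number_doses = 1), "central_increase_on_dose")
  expect_error(dose_schedule(max_number_doses = 2, dose_interval = -5,
                             central_increase_on_dose = 1),
               "dose_interval")
  expect_error(dose_schedule(max_number_doses = 1, number_loading_doses = 2,
                             central_increase_on_dose = 1),
               "number_loading_doses")
  expect_warning(sch <- dose_schedule(max_number_doses = 2,
                                      number_loading_doses = 1,
                                      dose_interval = 60,
                                      central_increase_on_dose = 7),
                 "loading")
  expect_equal(sch$central_increase_on_loading_dose, 7)
})
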