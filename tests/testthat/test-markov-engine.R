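test_that("discount factors follow the compound-monthly closed form", {
  expect_equal(monthly_discount_factor(0.03, 0), 1.0)
  expect_equal(monthly_discount_factor(0.03, 12), 1 / 1.03)
  expect_equal(monthly_discount_factor(0.03, 12), 0.970873786408,
               tolerance = 1e-10)
  expect_equal(monthly_discount_factor(0, 0:100), rep(1, 101))
  expect_equal(monthly_discount_factor(0.03, 12, "simple_monthly"),
               (1 + 0.03 / 12)^-12)
  expect_error(monthly_discount_factor(0.03, -1), class = "markovcea_invalid")
})

test_that("a forced two-cycle chain accrues one month in each living state", {
  s <- flat_strategy()
  tmat <- structure(list(p_sd_to_pd = 1, p_sd_to_dead = 0, p_pd_to_dead = 1,
                         structure = "progression_required"),
                    class = "transition_matrix")
  tr <- run_cohort(s, cea_settings(annual_discount_rate = 0), tmat = tmat)
  expect_equal(attr(tr, "n_cycles"), 2L)
  expect_equal(attr(tr, "total_qaly"), (0.85 + 0.65) / 12)
})

test_that("trace occupancies are conserved and death is monotone", {
  for (nm in analysis1$strategies$name) {
    st <- analysis1$strategies[analysis1$strategies$name == nm, ]
    tr <- run_cohort(st, analysis1$settings)
    occ_sum <- tr$occupancy_sd + tr$occupancy_pd + tr$occupancy_dead
    expect_true(all(abs(occ_sum - 1) < 1e-9))
    expect_true(all(diff(tr$occupancy_dead) >= 0))
    expect_true(all(tr$occupancy_sd >= 0 & tr$occupancy_pd >= 0))
    # totals equal the column sums of discounted per-cycle values
    expect_equal(attr(tr, "total_cost"), sum(tr$cycle_cost), tolerance = 1e-12)
    expect_equal(attr(tr, "total_qaly"), sum(tr$cycle_qaly), tolerance = 1e-12)
  }
})

test_that("undiscounted life expectancy matches the geometric closed form", {
  ras_bev <- analysis1$strategies[analysis1$strategies$name == "RAS-Bev", ]
  s0 <- cea_settings(annual_discount_rate = 0, horizon_cycles = 5000,
                     stop_dead_fraction = 1 - 1e-12)
  tr <- run_cohort(ras_bev, s0)
  tmat <- attr(tr, "tmat")
  life_trace <- sum(tr$occupancy_sd + tr$occupancy_pd)
  life_chain <- 1 / tmat$p_sd_to_pd + 1 / tmat$p_pd_to_dead
  expect_equal(life_trace, life_chain, tolerance = 0.005)
})

test_that("the symmetric half-life chain yields 0.25 undiscounted QALYs", {
  tmat <- build_transition_matrix(1, 2)
  costs <- list(cost_sd_first_cycle = 0, cost_sd_per_cycle = 0,
                cost_pd_per_cycle = 0)
  cf <- closed_form_expectation(tmat, costs, 0.85, 0.65, annual_rate = 0)
  expect_equal(cf$sd_cycles, 2)
  expect_equal(cf$pd_cycles, 2)
  expect_equal(cf$expected_qaly, (2 * 0.85 + 2 * 0.65) / 12)
  expect_equal(cf$expected_qaly, 0.25)
  # zero utilities give zero QALYs
  cf0 <- closed_form_expectation(tmat, costs, 0, 0, annual_rate = 0)
  expect_equal(cf0$expected_qaly, 0)
})

test_that("engine totals match the analytic expectation for both structures", {
  for (structure in c("progression_required", "direct_death")) {
    s <- flat_strategy()
    settings <- cea_settings(transition_structure = structure,
                             horizon_cycles = 2000,
                             stop_dead_fraction = 1 - 1e-10)
    tr <- run_cohort(s, settings)
    g <- glance(tr)
    tmat <- attr(tr, "tmat")
    cf <- closed_form_expectation(tmat, build_state_costs(s), s$u_stable,
                                  s$u_progressive, annual_rate = 0.03,
                                  horizon = g$n_cycles)
    expect_equal(g$total_cost, cf$expected_cost, tolerance = 1e-10,
                 label = structure)
    expect_equal(g$total_qaly, cf$expected_qaly, tolerance = 1e-10)
  }
})

test_that("discounting shrinks totals and vanishing rates recover them", {
  s <- flat_strategy()
  base <- cea_settings(annual_discount_rate = 0.03)
  none <- cea_settings(annual_discount_rate = 0)
  g_d <- glance(run_cohort(s, base))
  g_u <- glance(run_cohort(s, none))
  expect_lt(g_d$total_cost, g_u$total_cost)
  expect_lt(g_d$total_qaly, g_u$total_qaly)
})

test_that("totals are insensitive to the horizon beyond the stop threshold", {
  s <- flat_strategy()
  g1 <- glance(run_cohort(s, cea_settings(horizon_cycles = 240)))
  g2 <- glance(run_cohort(s, cea_settings(horizon_cycles = 480)))
  expect_equal(g1$total_cost, g2$total_cost, tolerance = 1e-4)
  expect_equal(g1$total_qaly, g2$total_qaly, tolerance = 1e-4)
})

test_that("hitting the horizon unabsorbed records a truncation warning", {
  s <- flat_strategy(median_pfs = 50, median_os = 150)
  expect_warning(run_cohort(s, cea_settings(horizon_cycles = 24)),
                 class = "markovcea_truncated")
  tr <- suppressWarnings(run_cohort(s, cea_settings(horizon_cycles = 24)))
  expect_true(attr(tr, "truncated"))
})

test_that("half-cycle correction lowers accrual on a declining cohort", {
  s <- flat_strategy()
  g0 <- glance(run_cohort(s, cea_settings(half_cycle_correction = FALSE)))
  g1 <- glance(run_cohort(s, cea_settings(half_cycle_correction = TRUE)))
  expect_lt(g1$total_qaly, g0$total_qaly)
  expect_lt(g1$total_cost, g0$total_cost)
})

test_that("trace CSV export carries metadata and the per-cycle table", {
  f <- withr::local_tempfile(fileext = ".csv")
  tr <- run_cohort(analysis1$strategies[4, ], analysis1$settings)
  write_trace_csv(tr, f)
  lines <- readLines(f)
  expect_true(any(grepl("strategy: RAS-Bev", lines)))
  expect_true(any(grepl("p_sd_to_pd", lines)))
  body <- readr::read_csv(f, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(body), attr(tr, "n_cycles"))
})
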