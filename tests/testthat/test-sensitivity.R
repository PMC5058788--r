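test_that("parameter paths resolve into settings and strategy cells", {
  a <- set_param(analysis1, "RAS-Cetux.u_stable", 0.89)
  expect_equal(a$strategies$u_stable[a$strategies$name == "RAS-Cetux"], 0.89)
  expect_equal(analysis1$strategies$u_stable[3], 0.85) # original untouched
  a2 <- set_param(analysis1, "settings.annual_discount_rate", 0.05)
  expect_equal(a2$settings$annual_discount_rate, 0.05)
  expect_error(set_param(analysis1, "RAS-Cetux.no_such_field", 1),
               "no_such_field", class = "markovcea_invalid")
  expect_error(set_param(analysis1, "Nobody.u_stable", 1),
               class = "markovcea_invalid")
  # invariant-breaking values are rejected
  expect_error(set_param(analysis1, "RAS-Cetux.median_pfs_months", 40),
               class = "markovcea_invalid")
  expect_error(set_param(analysis1, "RAS-Cetux.u_progressive", 0.9),
               class = "markovcea_invalid")
})

test_that("raising the stable-state utility raises QALYs and lowers the ICER", {
  base <- glance(run_cohort(
    analysis1$strategies[analysis1$strategies$name == "RAS-Cetux", ],
    analysis1$settings))
  up <- set_param(analysis1, "RAS-Cetux.u_stable", 0.89)
  raised <- glance(run_cohort(
    up$strategies[up$strategies$name == "RAS-Cetux", ], up$settings))
  expect_gt(raised$total_qaly, base$total_qaly)

  tor <- one_way_dsa(analysis1,
                     ranges = tibble::tibble(parameter = "RAS-Cetux.u_stable",
                                             low = 0.85, base = 0.85,
                                             high = 0.89),
                     outcome = "icer_pair", target = "RAS-Cetux",
                     comparator = "RAS-Bev")
  expect_lt(tor$outcome_at_high, tor$outcome_at_low)
  expect_equal(tor$outcome_at_low, attr(tor, "base_outcome"))
})

test_that("degenerate ranges have zero spread and reproduce base outputs bit-identically", {
  base_out <- markovcea:::evaluate_outcome(analysis1, "cost_per_qaly",
                                           "RAS-Bev")
  tor <- one_way_dsa(analysis1,
                     ranges = tibble::tibble(
                       parameter = c("RAS-Bev.u_stable",
                                     "RAS-Bev.median_pfs_months"),
                       low = c(0.85, 11.3), base = c(0.85, 11.3),
                       high = c(0.85, 11.3)),
                     outcome = "cost_per_qaly", target = "RAS-Bev")
  expect_identical(tor$spread, c(0, 0))
  expect_identical(tor$outcome_at_low, rep(base_out, 2))
  expect_identical(tor$outcome_at_high, rep(base_out, 2))
})

test_that("outcomes are insensitive to parameters they cannot depend on", {
  # the comparator's AE duration cannot move the target's cost/QALY
  tor <- one_way_dsa(analysis1,
                     ranges = tibble::tibble(
                       parameter = "RAS-Bev.ae_duration_months",
                       low = 4, base = 7.39, high = 10),
                     outcome = "cost_per_qaly", target = "RAS-Cetux")
  expect_equal(tor$spread, 0)
})

test_that("two-point DSA spread matches a brute-force re-run", {
  rng <- tibble::tibble(parameter = "RAS-Bev.median_os_months",
                        low = 28, base = 31.2, high = 34)
  tor <- one_way_dsa(analysis1, ranges = rng, outcome = "icer_pair",
                     target = "RAS-Cetux", comparator = "RAS-Bev")
  manual <- function(v) {
    a <- set_param(analysis1, "RAS-Bev.median_os_months", v)
    st <- a$strategies
    gi <- glance(suppressWarnings(run_cohort(st[st$name == "RAS-Cetux", ],
                                             a$settings)))
    gc_ <- glance(suppressWarnings(run_cohort(st[st$name == "RAS-Bev", ],
                                              a$settings)))
    (gi$total_cost - gc_$total_cost) / (gi$total_qaly - gc_$total_qaly)
  }
  expect_equal(tor$outcome_at_low, manual(28))
  expect_equal(tor$outcome_at_high, manual(34))
  expect_equal(tor$spread, abs(manual(34) - manual(28)))
})

test_that("default ranges honour invariants and sort by spread", {
  rng <- default_dsa_ranges(analysis1)
  expect_true(all(rng$low <= rng$base & rng$base <= rng$high))
  u_rows <- rng[grepl("u_stable", rng$parameter), ]
  expect_true(all(u_rows$high <= 1))
  tor <- one_way_dsa(analysis1, ranges = rng[1:6, ],
                     outcome = "cost_per_qaly", target = "KRAS-Cetux")
  expect_true(all(diff(tor$spread) <= 0))
})

test_that("microsimulation is reproducible and degenerate chains have zero variance", {
  s <- flat_strategy()
  settings <- cea_settings()
  p1 <- microsimulate(s, settings, n_individuals = 200, n_trials = 5, seed = 11)
  p2 <- microsimulate(s, settings, n_individuals = 200, n_trials = 5, seed = 11)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- microsimulate(s, settings, n_individuals = 200, n_trials = 5, seed = 12)
  expect_false(identical(p1$mean_qaly, p3$mean_qaly))

  # degenerate chain: sub-cycle medians make both transitions certain, so
  # every individual spends exactly one cycle in each living state
  dead <- flat_strategy(median_pfs = 0.001, median_os = 0.002)
  det <- microsimulate(dead, cea_settings(annual_discount_rate = 0),
                       n_individuals = 50, n_trials = 4, seed = 3)
  expect_equal(stats::sd(det$mean_qaly), 0)
  expect_equal(unique(det$mean_qaly), (0.85 + 0.65) / 12)
  expect_equal(stats::sd(det$mean_cost), 0)
})

test_that("first-order grand means converge to the cohort expectation", {
  ras_bev <- analysis1$strategies[analysis1$strategies$name == "RAS-Bev", ]
  settings <- analysis1$settings
  settings$stop_dead_fraction <- 1 # run both to the same horizon
  tr <- suppressWarnings(run_cohort(ras_bev, settings))
  g <- glance(tr)
  psa <- microsimulate(ras_bev, settings, n_individuals = 2000,
                       n_trials = 20, seed = 5)
  for (col in c("mean_cost", "mean_qaly")) {
    grand <- mean(psa[[col]])
    se <- stats::sd(psa[[col]]) / sqrt(nrow(psa))
    target <- if (col == "mean_cost") g$total_cost else g$total_qaly
    expect_lt(abs(grand - target) / se, 3, label = col)
  }
})

test_that("second-order mode requires a parameter sampler", {
  s <- flat_strategy()
  expect_error(microsimulate(s, cea_settings(), 10, 2, 1,
                             mode = "second_order"),
               "param_sampler", class = "markovcea_invalid")
  sampler <- function(trial) flat_strategy(unit_price = 10 + trial)
  p <- microsimulate(s, cea_settings(), n_individuals = 50, n_trials = 3,
                     seed = 2, mode = "second_order",
                     param_sampler = sampler)
  expect_equal(nrow(p), 3)
})
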