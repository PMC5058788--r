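#' Specification for synthetic strategy generation
#'
#' Ranges from which synthetic strategies are drawn uniformly. Defaults
#' emulate the structure of the base case: median PFS of a few months to
#' two years, a positive post-progression survival offset, cost components
#' on the order of the first-line regimen costs, and utilities bracketing
#' the published 0.85/0.65 pair.
#'
#' @param n_strategies Number of strategies to draw.
#' @param median_pfs_range Months, `c(low, high)`; positive.
#' @param os_offset_range Post-progression months added to PFS; positive.
#' @param unit_price_range USD/mg for the biologic.
#' @param monitoring_range USD/cycle for administration/monitoring.
#' @param progression_cost_range USD/month after progression.
#' @param u_stable_range,u_progressive_range Utility ranges in `[0, 1]`.
#' @param seed Integer seed.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_strategies = 10,
                           median_pfs_range = c(4, 24),
                           os_offset_range = c(3, 30),
                           unit_price_range = c(1, 12),
                           monitoring_range = c(100, 1000),
                           progression_cost_range = c(500, 5000),
                           u_stable_range = c(0.7, 0.95),
                           u_progressive_range = c(0.4, 0.7),
                           seed = 1) {
  spec <- list(n_strategies = n_strategies,
               median_pfs_range = median_pfs_range,
               os_offset_range = os_offset_range,
               unit_price_range = unit_price_range,
               monitoring_range = monitoring_range,
               progression_cost_range = progression_cost_range,
               u_stable_range = u_stable_range,
               u_progressive_range = u_progressive_range,
               seed = seed)
  assert_scalar_number(n_strategies, "n_strategies", min = 1)
  for (nm in grep("_range$", names(spec), value = TRUE)) {
    r <- spec[[nm]]
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      abort_invalid(sprintf("`%s` must be c(low, high) with low <= high.", nm))
    }
  }
  if (any(spec$median_pfs_range <= 0) || any(spec$os_offset_range <= 0)) {
    abort_invalid("median and offset ranges must be positive.")
  }
  if (any(unlist(spec[c("u_stable_range", "u_progressive_range")]) < 0) ||
      any(unlist(spec[c("u_stable_range", "u_progressive_range")]) > 1)) {
    abort_invalid("utility ranges must lie in [0, 1].")
  }
  if (spec$u_progressive_range[1] > spec$u_stable_range[2]) {
    abort_invalid("utility ranges make u_progressive <= u_stable infeasible.")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate synthetic strategies with closed-form ground truth
#'
#' Draws strategy parameters uniformly within the ranges of a
#' [synthetic_spec()] and attaches, per strategy, the expected discounted
#' cost and QALYs from [closed_form_expectation()] plus the true dominance
#' frontier over those expectations — so every downstream stage can be
#' checked against known answers. Generation is deterministic given the
#' spec's seed, and every generated strategy satisfies the full strategy
#' schema (they round-trip through [write_analysis_config()] /
#' [load_analysis_config()]).
#'
#' @param spec A [synthetic_spec()].
#' @param settings A [cea_settings()] list used for the ground-truth
#'   expectations (infinite-horizon closed form uses its discount rate).
#' @return List with `analysis` (a `cea_analysis`) and `ground_truth`
#'   (tibble: `name`, `expected_cost`, `expected_qaly`, `on_frontier`).
#' @export
generate_strategies <- function(spec = synthetic_spec(),
                                settings = cea_settings()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  settings <- validate_settings(settings)
  set.seed(derive_seed(spec$seed, 0L))
  n <- spec$n_strategies
  draw <- function(r) runif(n, r[1], r[2])
  u_stable <- draw(spec$u_stable_range)
  u_prog <- pmin(draw(spec$u_progressive_range), u_stable)
  pfs <- draw(spec$median_pfs_range)
  weekly <- runif(n) < 0.5
  st <- tibble(
    name = sprintf("synthetic-%02d", seq_len(n)),
    biomarker_policy = "extended_RAS_wt",
    biologic = ifelse(weekly, "Cetux", "Bev"),
    backbone = "pooled",
    median_pfs_months = pfs,
    median_os_months = pfs + draw(spec$os_offset_range),
    u_stable = u_stable,
    u_progressive = u_prog,
    bsa_m2 = 1.60,
    body_weight_kg = 58,
    biologic_dose_per_bsa_mg_m2 = ifelse(weekly, 250, NA_real_),
    biologic_dose_per_kg_mg_kg = ifelse(weekly, NA_real_, 5),
    biologic_loading_dose_per_bsa_mg_m2 = ifelse(weekly, 400, NA_real_),
    biologic_schedule_days = ifelse(weekly, 7, 14),
    backbone_schedule_days = 14,
    biologic_unit_price_usd_per_mg = draw(spec$unit_price_range),
    backbone_cost_per_admin_usd = runif(n, 800, 1500),
    admin_monitoring_cost_per_cycle_usd = draw(spec$monitoring_range),
    progression_cost_per_month_usd = draw(spec$progression_cost_range),
    travel_cost_per_visit_usd = 8.0,
    absenteeism_cost_per_day_usd = 18.94,
    absenteeism_days_per_visit = 1,
    ae_duration_months = pmax(pfs * 0.8, 1),
    ae_profile = map(seq_len(n), function(i) {
      tibble(event = c("hematologic", "diarrhea"),
             incidence = runif(2, 0, 0.4),
             unit_cost_usd = runif(2, 100, 3000),
             status = "assumed")
    }))
  class(st) <- c("cea_strategies", class(st))
  analysis <- structure(list(settings = settings, strategies = st),
                        class = "cea_analysis")

  gt <- bind_rows(map(seq_len(n), function(i) {
    row <- st[i, ]
    tmat <- build_transition_matrix(row$median_pfs_months,
                                    row$median_os_months,
                                    structure = settings$transition_structure)
    cf <- closed_form_expectation(
      tmat, build_state_costs(row), row$u_stable, row$u_progressive,
      annual_rate = settings$annual_discount_rate,
      conversion = settings$discount_conversion)
    tibble(name = row$name, expected_cost = cf$expected_cost,
           expected_qaly = cf$expected_qaly)
  }))
  dom <- classify_dominance(gt |>
                              rename(total_cost = "expected_cost",
                                     total_qaly = "expected_qaly"))
  gt$on_frontier <- dom$on_frontier[match(gt$name, dom$name)]
  list(analysis = analysis, ground_truth = gt)
}

#' Sample exponential event times with a given median
#'
#' The continuous counterpart of the median-to-probability conversion: an
#' exponential distribution with rate `log(2)/median` has exactly the
#' stated median, and discretising its event times into monthly cycles
#' recovers the per-cycle transition probability.
#'
#' @param n Number of draws.
#' @param median_months Median event time in months; positive.
#' @param seed Integer seed.
#' @return Numeric vector of event times in months.
#' @export
exponential_event_sampler <- function(n, median_months, seed = 1) {
  assert_scalar_number(n, "n", min = 1)
  assert_scalar_number(median_months, "median_months", min = 1e-12)
  set.seed(derive_seed(seed, 0L))
  rexp(n, rate = log(2) / median_months)
}
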