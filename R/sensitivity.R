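# Parameter paths are dot-addressed: "settings.<field>" or
# "<strategy name>.<column>", e.g. "RAS-Cetux.u_stable".

#' Set a single parameter of an analysis by path
#'
#' @param analysis A `cea_analysis` list.
#' @param path Dot-addressed parameter path: `"settings.<field>"` or
#'   `"<strategy name>.<column>"`.
#' @param value New numeric value; strategy invariants are re-validated.
#' @return The modified `cea_analysis`.
#' @export
set_param <- function(analysis, path, value) {
  stopifnot(inherits(analysis, "cea_analysis"))
  dot <- regexpr(".", path, fixed = TRUE)
  if (dot < 0) {
    abort_invalid(sprintf("parameter path '%s' has no '.' separator.", path))
  }
  scope <- substr(path, 1L, dot - 1L)
  field <- substr(path, dot + 1L, nchar(path))
  if (scope == "settings") {
    if (!field %in% SETTINGS_FIELDS) {
      abort_invalid(sprintf("unresolvable parameter path '%s'.", path))
    }
    analysis$settings[[field]] <- value
    analysis$settings <- validate_settings(analysis$settings)
    return(analysis)
  }
  st <- analysis$strategies
  i <- which(st$name == scope)
  if (length(i) != 1L || !field %in% names(st) || field == "ae_profile") {
    abort_invalid(sprintf("unresolvable parameter path '%s'.", path))
  }
  st[[field]][i] <- value
  check_strategy_row(st[i, ])
  analysis$strategies <- st
  analysis
}

get_param <- function(analysis, path) {
  dot <- regexpr(".", path, fixed = TRUE)
  scope <- substr(path, 1L, dot - 1L)
  field <- substr(path, dot + 1L, nchar(path))
  if (scope == "settings") return(analysis$settings[[field]])
  st <- analysis$strategies
  st[[field]][st$name == scope]
}

# re-check the invariants a single-cell edit can break
check_strategy_row <- function(row) {
  if (row$median_os_months <= row$median_pfs_months) {
    abort_invalid("`median_os_months` must exceed `median_pfs_months`.")
  }
  if (row$u_progressive < 0 || row$u_stable > 1 ||
      row$u_progressive > row$u_stable) {
    abort_invalid("utilities must satisfy 0 <= u_progressive <= u_stable <= 1.")
  }
  invisible(row)
}

#' Default one-way sensitivity ranges
#'
#' When no range table is supplied, each varied parameter gets low/high at
#' +/-20% of its base value, truncated where invariants bind (utilities at
#' 1 and at each other; median PFS below median OS).
#'
#' @param analysis A `cea_analysis` list.
#' @param parameters Character vector of strategy columns to vary (default:
#'   medians, utilities and main cost cells) for every strategy, plus the
#'   annual discount rate.
#' @param rel Half-width of the relative range (default 0.2).
#' @return Tibble with `parameter`, `low`, `base`, `high`.
#' @export
default_dsa_ranges <- function(analysis,
                               parameters = c("median_pfs_months",
                                              "median_os_months",
                                              "u_stable", "u_progressive",
                                              "biologic_unit_price_usd_per_mg",
                                              "progression_cost_per_month_usd",
                                              "admin_monitoring_cost_per_cycle_usd"),
                               rel = 0.2) {
  st <- analysis$strategies
  rows <- list(tibble(parameter = "settings.annual_discount_rate",
                      base = analysis$settings$annual_discount_rate) |>
                 mutate(low = .data$base * (1 - rel),
                        high = .data$base * (1 + rel)))
  for (i in seq_len(nrow(st))) {
    for (f in parameters) {
      base <- st[[f]][i]
      low <- base * (1 - rel)
      high <- base * (1 + rel)
      if (f == "u_stable") high <- min(high, 1)
      if (f == "u_progressive") high <- min(high, st$u_stable[i])
      if (f == "u_stable") low <- max(low, st$u_progressive[i])
      if (f == "median_pfs_months") {
        high <- min(high, st$median_os_months[i] * 0.999)
      }
      if (f == "median_os_months") {
        low <- max(low, st$median_pfs_months[i] * 1.001)
      }
      rows <- c(rows, list(tibble(
        parameter = paste0(st$name[i], ".", f),
        base = base, low = low, high = high)))
    }
  }
  bind_rows(rows) |> select("parameter", "low", "base", "high")
}

evaluate_outcome <- function(analysis, outcome, target, comparator = NULL) {
  st <- analysis$strategies
  run1 <- function(nm) {
    i <- which(st$name == nm)
    if (length(i) != 1L) abort_invalid(sprintf("unknown strategy '%s'.", nm))
    # extreme sensitivity values may push the cohort past the horizon;
    # the cap applying there is expected, not worth a warning per re-run
    withCallingHandlers(
      glance(run_cohort(st[i, ], analysis$settings)),
      markovcea_truncated = function(w) invokeRestart("muffleWarning"))
  }
  g_t <- run1(target)
  if (outcome == "cost_per_qaly") {
    return(cost_per_qaly(g_t$total_cost, g_t$total_qaly))
  }
  if (is.null(comparator)) {
    abort_invalid("`comparator` is required for the icer_pair outcome.")
  }
  icer(g_t, run1(comparator))$icer
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full pipeline once with each parameter at its low and once
#' at its high value, holding everything else at base, and records the
#' outcome spread. The outcome is either a strategy's cost per QALY or the
#' ICER of `comparator` versus `target` (intervention vs reference). The
#' evaluation is deterministic; with `low = base = high` the spread is
#' exactly zero and the outcomes are bit-identical to the base case.
#'
#' @param analysis A `cea_analysis` list.
#' @param ranges Tibble with `parameter` (dot-addressed path), `low`,
#'   `high` and optionally `base` (read from the analysis when absent);
#'   defaults to [default_dsa_ranges()]. Must satisfy `low <= base <= high`.
#' @param outcome `"cost_per_qaly"` or `"icer_pair"`.
#' @param target Strategy whose outcome is tracked; for `icer_pair` this is
#'   the intervention arm.
#' @param comparator For `icer_pair`: the reference arm of the ICER.
#' @return A `cea_tornado` tibble: `parameter`, `low`, `base`, `high`,
#'   `outcome_at_low`, `outcome_at_high`, `spread`, sorted by descending
#'   spread; base-case outcome in the `"base_outcome"` attribute.
#' @export
one_way_dsa <- function(analysis, ranges = NULL,
                        outcome = c("cost_per_qaly", "icer_pair"),
                        target, comparator = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(analysis, "cea_analysis"))
  if (is.null(ranges)) ranges <- default_dsa_ranges(analysis)
  ranges <- as_tibble(ranges)
  if (!all(c("parameter", "low", "high") %in% names(ranges))) {
    abort_invalid("`ranges` needs columns parameter, low, high.")
  }
  if (!"base" %in% names(ranges)) {
    ranges$base <- map_dbl(ranges$parameter,
                           function(p) get_param(analysis, p))
  }
  if (any(ranges$low > ranges$base | ranges$base > ranges$high)) {
    abort_invalid("ranges must satisfy low <= base <= high.")
  }
  base_outcome <- evaluate_outcome(analysis, outcome, target, comparator)
  at <- function(p, v) {
    evaluate_outcome(set_param(analysis, p, v), outcome, target, comparator)
  }
  entries <- ranges |>
    mutate(outcome_at_low = map_dbl(seq_len(dplyr::n()), function(k) {
             at(ranges$parameter[k], ranges$low[k])
           }),
           outcome_at_high = map_dbl(seq_len(dplyr::n()), function(k) {
             at(ranges$parameter[k], ranges$high[k])
           }),
           spread = abs(.data$outcome_at_high - .data$outcome_at_low)) |>
    arrange(desc(.data$spread))
  structure(entries, class = c("cea_tornado", class(entries)),
            base_outcome = base_outcome, outcome = outcome,
            target = target, comparator = comparator)
}

#' Tornado diagram
#'
#' @param object A `cea_tornado`.
#' @param n_top Number of widest entries to draw (default 12).
#' @param ... Unused.
#' @return A ggplot with one horizontal bar per parameter spanning the
#'   outcome between its low and high evaluations.
#' @export
autoplot.cea_tornado <- function(object, n_top = 12, ...) {
  df <- as_tibble(unclass(object))[seq_len(min(n_top, nrow(object))), ]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(object, "base_outcome")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_at_low,
                                       xend = .data$outcome_at_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = attr(object, "outcome"), y = NULL)
}

#' Monte Carlo microsimulation of individual patients
#'
#' First-order simulation: fixed parameters, individual state paths sampled
#' by monthly Bernoulli transitions through the three-state model, with
#' the same accrual conventions as [run_cohort()] (cycle-start accrual,
#' loading increment at cycle 0, per-cycle discounting, horizon cap). The
#' per-trial output is the mean discounted cost and QALYs over
#' `n_individuals`; across many individuals these converge to the cohort
#' trace totals. Second-order mode additionally redraws parameters each
#' trial via a user-supplied sampler. Per-trial RNG substreams are derived
#' deterministically from `(seed, trial)`, so runs are reproducible.
#'
#' @param strategy One-row strategy tibble.
#' @param settings A [cea_settings()] list (half-cycle correction is not
#'   available for individual sampling).
#' @param n_individuals Individuals per trial (base case 10,000).
#' @param n_trials Number of trials (base case 1,000).
#' @param seed Integer master seed.
#' @param mode `"first_order"` (default) or `"second_order"`.
#' @param param_sampler For second-order mode: `function(trial)` returning
#'   a one-row strategy tibble drawn from the parameter distributions.
#' @return A `cea_psa` tibble: `trial`, `mean_cost`, `mean_qaly`; the seed
#'   and settings are attached as attributes.
#' @export
microsimulate <- function(strategy, settings = cea_settings(),
                          n_individuals = 10000, n_trials = 1000,
                          seed = 1,
                          mode = c("first_order", "second_order"),
                          param_sampler = NULL) {
  mode <- match.arg(mode)
  settings <- validate_settings(settings)
  if (isTRUE(settings$half_cycle_correction)) {
    abort_invalid("microsimulation supports cycle-start accrual only.")
  }
  if (mode == "second_order" && is.null(param_sampler)) {
    abort_invalid("second-order mode needs a `param_sampler` distribution.")
  }
  assert_scalar_number(n_individuals, "n_individuals", min = 1)
  assert_scalar_number(n_trials, "n_trials", min = 1)

  horizon <- as.integer(settings$horizon_cycles)
  disc <- monthly_discount_factor(settings$annual_discount_rate,
                                  0:(horizon - 1L),
                                  settings$discount_conversion)

  prep <- function(strat) {
    tmat <- build_transition_matrix(strat$median_pfs_months,
                                    strat$median_os_months,
                                    structure = settings$transition_structure)
    costs <- build_state_costs(strat)
    list(p_spd = tmat$p_sd_to_pd, p_sdd = tmat$p_sd_to_dead,
         p_pdd = tmat$p_pd_to_dead,
         state_cost = c(costs$cost_sd_per_cycle, costs$cost_pd_per_cycle, 0),
         loading = costs$cost_sd_first_cycle - costs$cost_sd_per_cycle,
         state_qaly = c(strat$u_stable, strat$u_progressive, 0) / 12)
  }
  base_pars <- prep(strategy[1, ])

  one_trial <- function(trial) {
    set.seed(derive_seed(seed, trial))
    pars <- if (mode == "second_order") prep(param_sampler(trial)[1, ]) else
      base_pars
    state <- rep(1L, n_individuals)
    cost <- rep(pars$loading, n_individuals)
    qaly <- numeric(n_individuals)
    for (t in seq_len(horizon)) {
      alive <- state != 3L
      if (!any(alive)) break
      cost[alive] <- cost[alive] + pars$state_cost[state[alive]] * disc[t]
      qaly[alive] <- qaly[alive] + pars$state_qaly[state[alive]] * disc[t]
      u <- runif(sum(alive))
      st_a <- state[alive]
      sd <- st_a == 1L
      new <- st_a
      new[sd & u < pars$p_spd] <- 2L
      new[sd & u >= pars$p_spd & u < pars$p_spd + pars$p_sdd] <- 3L
      new[!sd & u < pars$p_pdd] <- 3L
      state[alive] <- new
    }
    c(mean_cost = mean(cost), mean_qaly = mean(qaly))
  }
  draws <- map(seq_len(n_trials), one_trial)
  out <- tibble(trial = seq_len(n_trials),
                mean_cost = map_dbl(draws, "mean_cost"),
                mean_qaly = map_dbl(draws, "mean_qaly"))
  structure(out, class = c("cea_psa", class(out)),
            seed = seed, n_individuals = n_individuals, mode = mode,
            settings = settings)
}

#' Scatter of per-trial Monte Carlo draws
#'
#' @param object A `cea_psa`.
#' @param ... Unused.
#' @return A ggplot of per-trial mean cost against mean QALYs.
#' @export
autoplot.cea_psa <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$mean_qaly, y = .data$mean_cost)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "Mean QALYs per trial", y = "Mean cost per trial (USD)")
}
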