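#' Per-cycle discount factor
#'
#' Costs and QALYs are discounted at an annual rate (base case 3%). With
#' `"compound_monthly"` conversion (default) the factor at monthly cycle
#' `t` is `(1 + annual)^(-t/12)`, the compound-equivalent monthly factor;
#' `"simple_monthly"` uses `(1 + annual/12)^(-t)`.
#'
#' @param annual_rate Annual discount rate as a fraction; non-negative.
#' @param cycle Cycle index (months since model start); non-negative,
#'   vectorised.
#' @param conversion `"compound_monthly"` or `"simple_monthly"`.
#' @return Discount factor(s) in (0, 1]; 1 at cycle 0 or zero rate.
#' @examples
#' monthly_discount_factor(0.03, 12) # 1/1.03
#' @export
monthly_discount_factor <- function(annual_rate, cycle,
                                    conversion = c("compound_monthly",
                                                   "simple_monthly")) {
  conversion <- match.arg(conversion)
  assert_scalar_number(annual_rate, "annual_rate", min = 0)
  if (any(cycle < 0)) abort_invalid("`cycle` must be non-negative.")
  if (conversion == "compound_monthly") {
    (1 + annual_rate)^(-cycle / 12)
  } else {
    (1 + annual_rate / 12)^(-cycle)
  }
}

#' Run the discounted Markov cohort trace for one strategy
#'
#' Propagates a cohort that starts entirely in stable disease (SD) through
#' the three-state model. Accrual happens at cycle start and transitions at
#' cycle end: in cycle `t` each state's occupancy accrues its per-cycle
#' cost and `utility/12` QALYs, both multiplied by the cycle-`t` discount
#' factor, after which the transition matrix is applied. The first cycle
#' adds the loading-dose cost increment. The trace stops once dead-state
#' occupancy reaches `stop_dead_fraction` or at `horizon_cycles`, whichever
#' comes first; hitting the horizon with the cohort not yet converged
#' raises a warning (class `markovcea_truncated`). With
#' `half_cycle_correction = TRUE` accrual uses the mean of start- and
#' end-of-cycle occupancy instead.
#'
#' @param strategy One-row strategy tibble.
#' @param settings A [cea_settings()] list.
#' @param tmat Optional [build_transition_matrix()] result; built from the
#'   strategy's medians when omitted.
#' @param costs Optional [build_state_costs()] result; built from the
#'   strategy when omitted.
#' @return A `cohort_trace`: tibble with one row per cycle (`cycle`,
#'   `occupancy_sd`, `occupancy_pd`, `occupancy_dead`, `discount_factor`,
#'   `cycle_cost`, `cycle_qaly`) carrying totals and run metadata as
#'   attributes; see [glance.cohort_trace()].
#' @export
run_cohort <- function(strategy, settings = cea_settings(), tmat = NULL,
                       costs = NULL) {
  settings <- validate_settings(settings)
  s <- strategy[1, ]
  if (is.null(tmat)) {
    tmat <- build_transition_matrix(s$median_pfs_months, s$median_os_months,
                                    structure = settings$transition_structure)
  }
  if (is.null(costs)) costs <- build_state_costs(s)

  horizon <- as.integer(settings$horizon_cycles)
  state_cost <- c(costs$cost_sd_per_cycle, costs$cost_pd_per_cycle, 0)
  loading <- costs$cost_sd_first_cycle - costs$cost_sd_per_cycle
  state_qaly <- c(s$u_stable, s$u_progressive, 0) / 12

  occ <- matrix(NA_real_, nrow = horizon + 1L, ncol = 3L)
  occ[1L, ] <- c(1, 0, 0)
  P <- as.matrix(tmat)
  n_cycles <- horizon
  for (t in seq_len(horizon)) {
    occ[t + 1L, ] <- occ[t, ] %*% P
    if (occ[t + 1L, 3L] >= settings$stop_dead_fraction) {
      n_cycles <- t
      break
    }
  }
  truncated <- occ[n_cycles + 1L, 3L] < settings$stop_dead_fraction
  if (truncated) {
    warn(sprintf(
      "cohort not absorbed at horizon (%d cycles): dead occupancy %.6f < %.6f; horizon cap applied.",
      horizon, occ[n_cycles + 1L, 3L], settings$stop_dead_fraction),
      class = "markovcea_truncated")
  }

  cycles <- 0:(n_cycles - 1L)
  occ_start <- occ[cycles + 1L, , drop = FALSE]
  occ_accrual <- occ_start
  if (isTRUE(settings$half_cycle_correction)) {
    occ_accrual <- (occ_start + occ[cycles + 2L, , drop = FALSE]) / 2
  }
  disc <- monthly_discount_factor(settings$annual_discount_rate, cycles,
                                  settings$discount_conversion)
  cycle_cost <- as.vector(occ_accrual %*% state_cost) * disc
  cycle_cost[1L] <- cycle_cost[1L] + loading * occ_accrual[1L, 1L] * disc[1L]
  cycle_qaly <- as.vector(occ_accrual %*% state_qaly) * disc

  trace <- tibble(
    cycle = cycles,
    occupancy_sd = occ_start[, 1L],
    occupancy_pd = occ_start[, 2L],
    occupancy_dead = occ_start[, 3L],
    discount_factor = disc,
    cycle_cost = cycle_cost,
    cycle_qaly = cycle_qaly)

  structure(trace,
            class = c("cohort_trace", class(trace)),
            strategy_name = if ("name" %in% names(s)) s$name else NA_character_,
            total_cost = sum(cycle_cost),
            total_qaly = sum(cycle_qaly),
            n_cycles = n_cycles,
            truncated = truncated,
            tmat = tmat,
            settings = settings)
}

#' @export
tidy.cohort_trace <- function(x, ...) as_tibble(unclass(x))

#' One-row summary of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Tibble with `name`, `total_cost`, `total_qaly`, `n_cycles`,
#'   `truncated`.
#' @export
glance.cohort_trace <- function(x, ...) {
  tibble(name = attr(x, "strategy_name"),
         total_cost = attr(x, "total_cost"),
         total_qaly = attr(x, "total_qaly"),
         n_cycles = attr(x, "n_cycles"),
         truncated = attr(x, "truncated"))
}

#' State-occupancy plot of a cohort trace
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot of state occupancy over cycles.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- tidy(object) |>
    select("cycle", "occupancy_sd", "occupancy_pd", "occupancy_dead") |>
    tidyr::pivot_longer(-"cycle", names_to = "state", names_prefix = "occupancy_",
                        values_to = "occupancy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle (months)", y = "Occupancy",
                  title = attr(object, "strategy_name"))
}

#' Run every strategy of an analysis through the cohort engine
#'
#' @param analysis A `cea_analysis` list.
#' @return Tibble of per-strategy engine totals (`name`, `total_cost`,
#'   `total_qaly`, `n_cycles`, `truncated`).
#' @export
run_strategies <- function(analysis) {
  stopifnot(inherits(analysis, "cea_analysis"))
  st <- analysis$strategies
  bind_rows(map(seq_len(nrow(st)), function(i) {
    glance(run_cohort(st[i, ], analysis$settings))
  }))
}

#' Closed-form expected discounted cost and QALYs
#'
#' Analytic oracle for the cohort engine. With per-cycle discount base `a`,
#' SD exit probability `p = p_sd_to_pd + p_sd_to_dead` and PD exit
#' probability `q = p_pd_to_dead`, the discounted occupancy sums over a
#' finite horizon `T` are geometric series:
#' `S_sd = G(a(1-p), T)` and
#' `S_pd = p_sd_to_pd * (G(a(1-q), T) - G(a(1-p), T)) / ((1-q) - (1-p))`
#' with `G(z, T) = (1 - z^T)/(1 - z)`, covering both transition structures
#' (SD-to-death mass simply never feeds PD). Expected cost is
#' `cost_sd * S_sd + loading_increment + cost_pd * S_pd`; expected QALYs
#' substitute `utility/12` for cost. Assumes accrual at cycle start without
#' half-cycle correction.
#'
#' @param tmat A [build_transition_matrix()] result.
#' @param costs A [build_state_costs()] result (or list with the same
#'   `cost_*` fields).
#' @param u_stable,u_progressive State utilities.
#' @param annual_rate Annual discount rate.
#' @param horizon Number of cycles (default `Inf`).
#' @param conversion Discount conversion, as in [monthly_discount_factor()].
#' @return List with `expected_cost`, `expected_qaly`, `sd_cycles`
#'   (discounted SD occupancy sum) and `pd_cycles`.
#' @export
closed_form_expectation <- function(tmat, costs, u_stable, u_progressive,
                                    annual_rate = 0.03, horizon = Inf,
                                    conversion = "compound_monthly") {
  a <- monthly_discount_factor(annual_rate, 1, conversion)
  p <- tmat$p_sd_to_pd + tmat$p_sd_to_dead
  q <- tmat$p_pd_to_dead
  if (p <= 0 || q <= 0) {
    abort_invalid("exit probabilities must be positive for a finite chain.")
  }
  G <- function(z, T) {
    if (abs(1 - z) < 1e-14) return(T)
    if (is.infinite(T)) 1 / (1 - z) else (1 - z^T) / (1 - z)
  }
  x <- 1 - p
  y <- 1 - q
  s_sd <- G(a * x, horizon)
  if (abs(x - y) > 1e-12) {
    s_pd <- tmat$p_sd_to_pd * (G(a * y, horizon) - G(a * x, horizon)) /
      (y - x)
  } else {
    # equal sojourn probabilities: occupancy_pd(t) = p_sd_pd * t * x^(t-1)
    T <- if (is.infinite(horizon)) 10000L else horizon
    t <- seq_len(T - 1L)
    s_pd <- tmat$p_sd_to_pd * sum(a^t * t * x^(t - 1L))
  }
  loading <- costs$cost_sd_first_cycle - costs$cost_sd_per_cycle
  list(
    expected_cost = costs$cost_sd_per_cycle * s_sd + loading +
      costs$cost_pd_per_cycle * s_pd,
    expected_qaly = (u_stable * s_sd + u_progressive * s_pd) / 12,
    sd_cycles = s_sd,
    pd_cycles = s_pd)
}

#' Export a cohort trace as CSV with header metadata
#'
#' Writes the per-cycle trace preceded by commented header lines recording
#' the strategy name, transition probabilities and run settings.
#'
#' @param trace A `cohort_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  tmat <- attr(trace, "tmat")
  settings <- attr(trace, "settings")
  header <- c(
    sprintf("# strategy: %s", attr(trace, "strategy_name")),
    sprintf("# p_sd_to_pd: %.12g  p_sd_to_dead: %.12g  p_pd_to_dead: %.12g",
            tmat$p_sd_to_pd, tmat$p_sd_to_dead, tmat$p_pd_to_dead),
    sprintf("# annual_discount_rate: %g  horizon_cycles: %d  stop_dead_fraction: %g",
            settings$annual_discount_rate,
            as.integer(settings$horizon_cycles), settings$stop_dead_fraction),
    sprintf("# total_cost: %.6f  total_qaly: %.6f",
            attr(trace, "total_cost"), attr(trace, "total_qaly")))
  writeLines(header, path)
  suppressWarnings(
    readr::write_csv(tidy(trace), path, append = TRUE, col_names = TRUE))
  invisible(path)
}
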