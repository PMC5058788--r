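#' Drug cost of one administration from dosing arithmetic
#'
#' Dose per administration is either body-surface-area based
#' (`dose_per_bsa` mg/m2 x `bsa` m2, as for Cetuximab) or weight based
#' (`dose_per_kg` mg/kg x `body_weight` kg, as for Bevacizumab); exactly one
#' of the two dose fields must be given. The cost is dose times a unit price
#' in USD per mg.
#'
#' @param unit_price_usd_per_mg Drug unit price, USD per mg; positive.
#' @param dose_per_bsa Dose in mg per m2 of body surface area, or `NULL`.
#' @param dose_per_kg Dose in mg per kg of body weight, or `NULL`.
#' @param bsa Body surface area in m2 (default 1.60, the modelled average).
#' @param body_weight Body weight in kg (default 58, the modelled mean).
#' @return Cost in USD of a single administration.
#' @examples
#' drug_cost_per_admin(7.568875, dose_per_bsa = 250) # Cetuximab regular dose
#' drug_cost_per_admin(8.996517, dose_per_kg = 5)    # Bevacizumab
#' @export
drug_cost_per_admin <- function(unit_price_usd_per_mg,
                                dose_per_bsa = NULL, dose_per_kg = NULL,
                                bsa = 1.60, body_weight = 58) {
  assert_scalar_number(unit_price_usd_per_mg, "unit_price_usd_per_mg",
                       min = 1e-12)
  has_bsa <- !is.null(dose_per_bsa) && !is.na(dose_per_bsa)
  has_kg <- !is.null(dose_per_kg) && !is.na(dose_per_kg)
  if (has_bsa == has_kg) {
    abort_invalid(
      "exactly one of `dose_per_bsa` / `dose_per_kg` must be given.")
  }
  if (has_bsa) {
    assert_scalar_number(dose_per_bsa, "dose_per_bsa", min = 0)
    assert_scalar_number(bsa, "bsa", min = 1e-9)
    dose_mg <- dose_per_bsa * bsa
  } else {
    assert_scalar_number(dose_per_kg, "dose_per_kg", min = 0)
    assert_scalar_number(body_weight, "body_weight", min = 1e-9)
    dose_mg <- dose_per_kg * body_weight
  }
  dose_mg * unit_price_usd_per_mg
}

#' Convert a per-administration cost to a monthly cost
#'
#' Regimens run on 7- or 14-day schedules while the model cycle is one
#' month; the conversion uses the average calendar month of 365.25/12 days,
#' so a weekly administration recurs 30.4375/7 times per cycle.
#'
#' @param cost_per_admin Cost of one administration, USD.
#' @param schedule_days Days between administrations; 7 or 14.
#' @return Cost in USD per monthly cycle.
#' @examples
#' admin_schedule_to_monthly(3027.55, 7)
#' admin_schedule_to_monthly(2608.99, 14)
#' @export
admin_schedule_to_monthly <- function(cost_per_admin, schedule_days) {
  assert_scalar_number(cost_per_admin, "cost_per_admin", min = 0)
  if (!schedule_days %in% c(7, 14)) {
    abort_invalid("`schedule_days` must be 7 or 14.")
  }
  cost_per_admin * DAYS_PER_MONTH / schedule_days
}

#' Monthly adverse-event cost from grade-3/4 incidences
#'
#' The expected per-patient cost of grade-3/4 adverse events is the
#' incidence-weighted sum of unit treatment costs, spread uniformly over the
#' on-treatment duration to give a per-cycle figure applied while patients
#' remain in the stable-disease (on-treatment) state.
#'
#' @param ae_profile Data frame with columns `event`, `incidence` (fractions
#'   in `[0, 1]`) and `unit_cost_usd`. An empty profile costs 0.
#' @param duration_months On-treatment duration over which the expected AE
#'   cost is spread; positive.
#' @return Cost in USD per month.
#' @export
ae_monthly_cost <- function(ae_profile, duration_months) {
  assert_scalar_number(duration_months, "duration_months", min = 1e-9)
  if (is.null(ae_profile) || nrow(ae_profile) == 0L) return(0)
  req <- c("event", "incidence", "unit_cost_usd")
  if (!all(req %in% names(ae_profile))) {
    abort_invalid(paste0("`ae_profile` needs columns: ",
                         paste(req, collapse = ", "), "."))
  }
  if (any(ae_profile$incidence < 0 | ae_profile$incidence > 1)) {
    abort_invalid("AE incidences must lie in [0, 1].")
  }
  if (any(ae_profile$unit_cost_usd < 0)) {
    abort_invalid("AE unit costs must be non-negative.")
  }
  sum(ae_profile$incidence * ae_profile$unit_cost_usd) / duration_months
}

#' Assemble per-cycle state costs for a strategy
#'
#' Builds the itemised cost profile the cohort engine consumes:
#'
#' * stable disease (SD), steady state: monthly biologic cost (dosing
#'   arithmetic x schedule), monthly backbone chemotherapy cost,
#'   administration/monitoring, societal costs (travel plus absenteeism per
#'   visit) and the monthly adverse-event cost;
#' * SD first cycle: adds the loading-dose increment when the biologic has
#'   a loading dose (Cetuximab's first administration at 400 rather than
#'   250 mg/m2);
#' * progressive disease (PD): the weighted subsequent-therapy cost per
#'   month plus the same monitoring and societal fees, which continue
#'   during progression.
#'
#' @param strategy One-row strategy tibble (a row of the table returned by
#'   [load_analysis_config()] or [base_case_analysis()]).
#' @return A `state_cost_profile`: list with `cost_sd_first_cycle`,
#'   `cost_sd_per_cycle`, `cost_pd_per_cycle` and a `components` tibble
#'   itemising every contribution (state, component, usd_per_cycle).
#' @export
build_state_costs <- function(strategy) {
  s <- as.list(strategy[1, ])
  s <- lapply(s, function(x) if (is.list(x)) x[[1]] else x)

  biologic_admin <- drug_cost_per_admin(
    s$biologic_unit_price_usd_per_mg,
    dose_per_bsa = if (is_set(s$biologic_dose_per_bsa_mg_m2))
      s$biologic_dose_per_bsa_mg_m2 else NULL,
    dose_per_kg = if (is_set(s$biologic_dose_per_kg_mg_kg))
      s$biologic_dose_per_kg_mg_kg else NULL,
    bsa = s$bsa_m2, body_weight = s$body_weight_kg)
  drug_monthly <- admin_schedule_to_monthly(biologic_admin,
                                            s$biologic_schedule_days)
  backbone_monthly <- admin_schedule_to_monthly(s$backbone_cost_per_admin_usd,
                                                s$backbone_schedule_days)

  # loading dose applies to the first administration only
  loading_increment <- 0
  if (is_set(s$biologic_loading_dose_per_bsa_mg_m2)) {
    loading_admin <- drug_cost_per_admin(
      s$biologic_unit_price_usd_per_mg,
      dose_per_bsa = s$biologic_loading_dose_per_bsa_mg_m2,
      bsa = s$bsa_m2)
    loading_increment <- loading_admin - biologic_admin
  }

  # visits follow the more frequent of the two schedules
  visit_days <- min(s$biologic_schedule_days, s$backbone_schedule_days)
  visits_per_month <- DAYS_PER_MONTH / visit_days
  societal_monthly <- (s$travel_cost_per_visit_usd +
                         s$absenteeism_cost_per_day_usd *
                         s$absenteeism_days_per_visit) * visits_per_month

  ae_monthly <- ae_monthly_cost(s$ae_profile, s$ae_duration_months)

  monitoring <- s$admin_monitoring_cost_per_cycle_usd
  sd_cycle <- drug_monthly + backbone_monthly + monitoring +
    societal_monthly + ae_monthly
  pd_cycle <- s$progression_cost_per_month_usd + monitoring + societal_monthly

  components <- tibble(
    state = c(rep("sd", 5), "sd_first_cycle", rep("pd", 3)),
    component = c("biologic_drug", "backbone_drug", "admin_monitoring",
                  "societal", "adverse_events", "loading_increment",
                  "progression_therapy", "admin_monitoring", "societal"),
    usd_per_cycle = c(drug_monthly, backbone_monthly, monitoring,
                      societal_monthly, ae_monthly, loading_increment,
                      s$progression_cost_per_month_usd, monitoring,
                      societal_monthly))

  structure(
    list(cost_sd_first_cycle = sd_cycle + loading_increment,
         cost_sd_per_cycle = sd_cycle,
         cost_pd_per_cycle = pd_cycle,
         components = components),
    class = "state_cost_profile")
}

is_set <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)

#' @export
print.state_cost_profile <- function(x, ...) {
  cat("Per-cycle state costs (USD)\n")
  cat(sprintf("  SD first cycle %12.2f\n", x$cost_sd_first_cycle))
  cat(sprintf("  SD per cycle   %12.2f\n", x$cost_sd_per_cycle))
  cat(sprintf("  PD per cycle   %12.2f\n", x$cost_pd_per_cycle))
  invisible(x)
}
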