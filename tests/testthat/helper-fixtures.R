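# cached fixtures shared across test files
analysis1 <- base_case_analysis(1)
analysis2 <- base_case_analysis(2)

published_results <- function(analysis) {
  tot <- base_case_totals(analysis)
  tibble::tibble(name = tot$name, total_cost = tot$total_cost_usd,
                 total_qaly = tot$total_qaly)
}

# a tiny deterministic strategy for unit tests, costs chosen round
flat_strategy <- function(median_pfs = 6, median_os = 18, u_stable = 0.85,
                          u_progressive = 0.65, unit_price = 10,
                          monitoring = 100, progression = 1000) {
  tibble::tibble(
    name = "unit-test", biomarker_policy = "extended_RAS_wt",
    biologic = "Bev", backbone = "pooled",
    median_pfs_months = median_pfs, median_os_months = median_os,
    u_stable = u_stable, u_progressive = u_progressive,
    bsa_m2 = 1.6, body_weight_kg = 58,
    biologic_dose_per_bsa_mg_m2 = NA_real_,
    biologic_dose_per_kg_mg_kg = 5,
    biologic_loading_dose_per_bsa_mg_m2 = NA_real_,
    biologic_schedule_days = 14, backbone_schedule_days = 14,
    biologic_unit_price_usd_per_mg = unit_price,
    backbone_cost_per_admin_usd = 1000,
    admin_monitoring_cost_per_cycle_usd = monitoring,
    progression_cost_per_month_usd = progression,
    travel_cost_per_visit_usd = 8, absenteeism_cost_per_day_usd = 18.94,
    absenteeism_days_per_visit = 1, ae_duration_months = 6,
    ae_profile = list(tibble::tibble(
      event = "hematologic", incidence = 0.2, unit_cost_usd = 600,
      status = "assumed")))
}
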