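# Analysis 2: FOLFOX vs FOLFIRI backbone crossed with
# Cetuximab/Bevacizumab in the extended RAS wild-type population.
# Backbone-specific median OS was published; backbone-specific PFS was not,
# so both backbones reuse the pooled extended-RAS-wt PFS (11.4 Cetux /
# 11.3 Bev), marked "assumed" in the provenance. Cost cells omitted here
# are filled from cost_calibration.yaml.
settings:
  cycle_length_months: 1
  horizon_cycles: 240
  stop_dead_fraction: 0.999
  half_cycle_correction: false
  annual_discount_rate: 0.03
  discount_conversion: compound_monthly
  transition_structure: progression_required
  wtp_threshold_usd_per_qaly: 20301
  currency_rate_cny_per_usd: 6.15
  seed: 1
strategies:
  - name: FOLFOX-Cetux
    biomarker_policy: extended_RAS_wt
    biologic: Cetux
    backbone: FOLFOX
    median_pfs_months: 11.4
    median_os_months: 32.5
    u_stable: 0.85
    u_progressive: 0.65
    bsa_m2: 1.60
    body_weight_kg: 58
    biologic_dose_per_bsa_mg_m2: 250
    biologic_loading_dose_per_bsa_mg_m2: 400
    biologic_schedule_days: 7
    backbone_schedule_days: 14
    travel_cost_per_visit_usd: 8.0
    absenteeism_cost_per_day_usd: 18.94
    absenteeism_days_per_visit: 1
  - name: FOLFOX-Bev
    biomarker_policy: extended_RAS_wt
    biologic: Bev
    backbone: FOLFOX
    median_pfs_months: 11.3
    median_os_months: 29.0
    u_stable: 0.85
    u_progressive: 0.65
    bsa_m2: 1.60
    body_weight_kg: 58
    biologic_dose_per_kg_mg_kg: 5
    biologic_schedule_days: 14
    backbone_schedule_days: 14
    travel_cost_per_visit_usd: 8.0
    absenteeism_cost_per_day_usd: 18.94
    absenteeism_days_per_visit: 1
  - name: FOLFIRI-Cetux
    biomarker_policy: extended_RAS_wt
    biologic: Cetux
    backbone: FOLFIRI
    median_pfs_months: 11.4
    median_os_months: 32.0
    u_stable: 0.85
    u_progressive: 0.65
    bsa_m2: 1.60
    body_weight_kg: 58
    biologic_dose_per_bsa_mg_m2: 250
    biologic_loading_dose_per_bsa_mg_m2: 400
    biologic_schedule_days: 7
    backbone_schedule_days: 14
    travel_cost_per_visit_usd: 8.0
    absenteeism_cost_per_day_usd: 18.94
    absenteeism_days_per_visit: 1
  - name: FOLFIRI-Bev
    biomarker_policy: extended_RAS_wt
    biologic: Bev
    backbone: FOLFIRI
    median_pfs_months: 11.3
    median_os_months: 35.2
    u_stable: 0.85
    u_progressive: 0.65
    bsa_m2: 1.60
    body_weight_kg: 58
    biologic_dose_per_kg_mg_kg: 5
    biologic_schedule_days: 14
    backbone_schedule_days: 14
    travel_cost_per_visit_usd: 8.0
    absenteeism_cost_per_day_usd: 18.94
    absenteeism_days_per_visit: 1
provenance:
  - {field: median_pfs_months, status: assumed, note: "pooled extended-RAS-wt PFS (11.4 Cetux / 11.3 Bev) reused for both backbones; backbone-specific PFS unpublished"}
  - {field: median_os_months, status: published, note: "CALGB 80405 backbone-specific median OS: FOLFOX 32.5 Cetux / 29.0 Bev; FOLFIRI 32.0 Cetux / 35.2 Bev"}
  - {field: u_stable, status: published, note: "literature utility 0.85 for stable disease"}
  - {field: u_progressive, status: published, note: "literature utility 0.65 for progressive disease"}
  - {field: bsa_m2, status: published, note: "modelled average body surface area 1.60 m2"}
  - {field: body_weight_kg, status: published, note: "modelled mean body weight 58 kg"}
  - {field: biologic_dose_per_bsa_mg_m2, status: published, note: "Cetuximab 250 mg/m2 weekly after a 400 mg/m2 loading dose"}
  - {field: biologic_dose_per_kg_mg_kg, status: published, note: "Bevacizumab 5 mg/kg every 14 days"}
  - {field: biologic_schedule_days, status: published, note: "weekly Cetuximab; biweekly Bevacizumab"}
  - {field: backbone_schedule_days, status: published, note: "FOLFOX/FOLFIRI on 14-day cycles"}
  - {field: travel_cost_per_visit_usd, status: published, note: "8.0 USD per visit, Sichuan taxi fare"}
  - {field: absenteeism_cost_per_day_usd, status: published, note: "18.94 USD per day, Sichuan median salary"}
  - {field: absenteeism_days_per_visit, status: assumed, note: "one absenteeism day per treatment visit"}
  - {field: settings.annual_discount_rate, status: published, note: "costs and benefits discounted at 3% annually"}
  - {field: settings.wtp_threshold_usd_per_qaly, status: published, note: "20,301 USD/QALY, triple the Chinese per-capita GDP"}
  - {field: settings.currency_rate_cny_per_usd, status: published, note: "exchange rate 1 USD = 6.15 CNY"}
  - {field: settings.horizon_cycles, status: assumed, note: "lifetime horizon operationalised as 240 monthly cycles with 0.999 dead-occupancy stop"}
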