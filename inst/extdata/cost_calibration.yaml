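# Cost calibration for the base-case fixtures.
#
# Cells the published base case did not itemise live here so they stay
# editable and clearly labelled, never silently invented. status is one of:
#   published - the value itself was published
#   derived   - solved from published aggregates (note says how)
#   assumed   - a stated modelling assumption
items:
  unit_price_usd_per_mg.Cetux:
    value: 7.568875
    status: derived
    note: "published regular administration cost 3027.55 USD / 400 mg (250 mg/m2 x 1.60 m2)"
  unit_price_usd_per_mg.Bev:
    value: 8.99651724137931
    status: derived
    note: "published administration cost 2608.99 USD / 290 mg (5 mg/kg x 58 kg)"
  backbone_cost_per_admin_usd.FOLFOX:
    value: 1275.69
    status: published
    note: "FOLFOX cost per 2-week administration"
  backbone_cost_per_admin_usd.FOLFIRI:
    value: 1171.77
    status: published
    note: "FOLFIRI cost per 2-week administration"
  backbone_cost_per_admin_usd.pooled:
    value: 1223.73
    status: assumed
    note: "mean of the published FOLFOX and FOLFIRI biweekly costs (physician-choice backbone)"
  admin_monitoring_cost_per_cycle_usd:
    value: 500.0
    status: assumed
    note: "monthly administration, hospitalisation, venous access and monitoring fees; identical across strategies"
  progression_cost_per_month_usd:
    value: 3500.0
    status: assumed
    note: "weighted subsequent-therapy cost per month after progression (88% of patients treated; mix of FOLFIRI/FOLFOX/irinotecan +/- biologics)"
  ae_duration_months.Cetux:
    value: 8.455257693033793
    status: derived
    note: "implied on-treatment months: published total AE cost 895.75 / monthly 105.94 USD"
  ae_duration_months.Bev:
    value: 7.389873417721518
    status: derived
    note: "implied on-treatment months: published total AE cost 642.18 / monthly 86.90 USD"
ae_profiles:
  # grade-3/4 incidences as reported for CALGB 80405; hematologic unit cost
  # solved per arm so the incidence-weighted total matches the published
  # arm-level AE aggregate; remaining unit costs assumed
  Cetux:
    - {event: hematologic, incidence: 0.274, unit_cost_usd: 2978.649635036496, status: derived}
    - {event: neuropathy, incidence: 0.12, unit_cost_usd: 300.0, status: assumed}
    - {event: rash, incidence: 0.07, unit_cost_usd: 180.0, status: assumed}
    - {event: diarrhea, incidence: 0.11, unit_cost_usd: 250.0, status: assumed}
    - {event: hypertension, incidence: 0.01, unit_cost_usd: 150.0, status: assumed}
    - {event: gastrointestinal, incidence: 0.005, unit_cost_usd: 400.0, status: assumed}
  Bev:
    - {event: hematologic, incidence: 0.266, unit_cost_usd: 2111.578947368421, status: derived}
    - {event: neuropathy, incidence: 0.14, unit_cost_usd: 300.0, status: assumed}
    - {event: rash, incidence: 0.0, unit_cost_usd: 180.0, status: assumed}
    - {event: diarrhea, incidence: 0.08, unit_cost_usd: 250.0, status: assumed}
    - {event: hypertension, incidence: 0.07, unit_cost_usd: 150.0, status: assumed}
    - {event: gastrointestinal, incidence: 0.02, unit_cost_usd: 400.0, status: assumed}
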