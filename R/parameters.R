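# Config schema: top-level keys, model settings and per-strategy fields.
# Unknown keys are rejected everywhere; cost cells missing from a strategy
# are filled from the cost-calibration file.

SETTINGS_FIELDS <- c("cycle_length_months", "horizon_cycles",
                     "stop_dead_fraction", "half_cycle_correction",
                     "annual_discount_rate", "discount_conversion",
                     "transition_structure", "wtp_threshold_usd_per_qaly",
                     "currency_rate_cny_per_usd", "seed")

SETTINGS_DEFAULTS <- list(
  cycle_length_months = 1,
  horizon_cycles = 240,
  stop_dead_fraction = 0.999,
  half_cycle_correction = FALSE,
  annual_discount_rate = 0.03,
  discount_conversion = "compound_monthly",
  transition_structure = "progression_required",
  wtp_threshold_usd_per_qaly = 20301,
  currency_rate_cny_per_usd = 6.15,
  seed = 1L)

STRATEGY_REQUIRED <- c(
  "name", "biomarker_policy", "biologic", "backbone",
  "median_pfs_months", "median_os_months", "u_stable", "u_progressive",
  "bsa_m2", "body_weight_kg", "biologic_schedule_days",
  "backbone_schedule_days", "travel_cost_per_visit_usd",
  "absenteeism_cost_per_day_usd", "absenteeism_days_per_visit")

STRATEGY_OPTIONAL <- c(
  "biologic_dose_per_bsa_mg_m2", "biologic_dose_per_kg_mg_kg",
  "biologic_loading_dose_per_bsa_mg_m2",
  # cost cells fillable from the calibration file
  "biologic_unit_price_usd_per_mg", "backbone_cost_per_admin_usd",
  "admin_monitoring_cost_per_cycle_usd", "progression_cost_per_month_usd",
  "ae_duration_months", "ae_profile")

CALIBRATED_FIELDS <- c(
  "biologic_unit_price_usd_per_mg", "backbone_cost_per_admin_usd",
  "admin_monitoring_cost_per_cycle_usd", "progression_cost_per_month_usd",
  "ae_duration_months")

#' Model settings
#'
#' Builds and validates the run settings of the cohort model: a 1-month
#' cycle, a lifetime horizon operationalised as `horizon_cycles` (default
#' 240 cycles = 20 years) with early stopping once the dead-state occupancy
#' reaches `stop_dead_fraction`, 3% annual discounting (compound-equivalent
#' monthly factor by default), and the willingness-to-pay threshold of
#' 20,301 USD/QALY (triple the Chinese per-capita GDP).
#'
#' @param ... Named settings overriding the defaults; unknown names are
#'   rejected. See `markovcea:::SETTINGS_DEFAULTS` for the full list.
#' @return A validated `cea_settings` list.
#' @examples
#' cea_settings()
#' cea_settings(annual_discount_rate = 0, horizon_cycles = 600)
#' @export
cea_settings <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), SETTINGS_FIELDS)
  if (length(unknown)) {
    abort_invalid(paste0("unknown settings field(s): ",
                         paste(unknown, collapse = ", ")))
  }
  s <- modifyList(SETTINGS_DEFAULTS, over)
  validate_settings(s)
}

validate_settings <- function(s) {
  unknown <- setdiff(names(s), SETTINGS_FIELDS)
  if (length(unknown)) {
    abort_invalid(paste0("unknown settings field(s): ",
                         paste(unknown, collapse = ", ")))
  }
  for (f in setdiff(SETTINGS_FIELDS, names(s))) s[[f]] <- SETTINGS_DEFAULTS[[f]]
  if (!identical(as.numeric(s$cycle_length_months), 1)) {
    abort_invalid("`cycle_length_months` is fixed at 1 month.")
  }
  assert_scalar_number(s$horizon_cycles, "horizon_cycles", min = 1)
  assert_scalar_number(s$stop_dead_fraction, "stop_dead_fraction",
                       min = 1e-12, max = 1)
  assert_scalar_number(s$annual_discount_rate, "annual_discount_rate", min = 0)
  assert_scalar_number(s$wtp_threshold_usd_per_qaly,
                       "wtp_threshold_usd_per_qaly", min = 1e-9)
  assert_scalar_number(s$currency_rate_cny_per_usd,
                       "currency_rate_cny_per_usd", min = 1e-9)
  if (!is.logical(s$half_cycle_correction) || is.na(s$half_cycle_correction)) {
    abort_invalid("`half_cycle_correction` must be TRUE or FALSE.")
  }
  if (!s$discount_conversion %in% c("compound_monthly", "simple_monthly")) {
    abort_invalid(
      "`discount_conversion` must be 'compound_monthly' or 'simple_monthly'.")
  }
  if (!s$transition_structure %in% c("progression_required", "direct_death")) {
    abort_invalid(
      "`transition_structure` must be 'progression_required' or 'direct_death'.")
  }
  structure(s[SETTINGS_FIELDS], class = "cea_settings")
}

#' @export
print.cea_settings <- function(x, ...) {
  cat("Cohort model settings\n")
  for (f in SETTINGS_FIELDS) cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML analysis configuration (model settings plus one entry per
#' treatment strategy), validates it against the schema — unknown keys are
#' rejected, every type invariant is enforced — and fills cost cells that
#' the configuration omits from the cost-calibration file.
#'
#' @param path Path to the analysis YAML file.
#' @param calibration Path to the cost-calibration YAML; defaults to the
#'   calibration shipped with the package. Required whenever a strategy
#'   omits a calibrated cost cell.
#' @return A `cea_analysis` list with elements `settings` (a
#'   [cea_settings()] list) and `strategies` (a tibble, one row per
#'   strategy, adverse-event profiles in the `ae_profile` list-column).
#'   Field-level provenance is attached as the `"provenance"` attribute of
#'   `strategies` and retrievable with [fixture_provenance()].
#' @seealso [base_case_analysis()] for the shipped base-case fixtures,
#'   [write_analysis_config()] for the inverse operation.
#' @export
load_analysis_config <- function(path, calibration = NULL) {
  if (!file.exists(path)) {
    abort_invalid(sprintf("config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("settings", "strategies", "provenance"))
  if (length(unknown)) {
    abort_invalid(paste0("unknown top-level key(s): ",
                         paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$strategies) || !length(raw$strategies)) {
    abort_invalid("config defines no strategies.")
  }
  settings <- validate_settings(raw$settings %||% list())

  needs_cal <- any(map_lgl(raw$strategies, function(s) {
    !all(CALIBRATED_FIELDS %in% names(s)) || !("ae_profile" %in% names(s))
  }))
  cal <- NULL
  if (needs_cal) {
    cal_path <- calibration %||% default_calibration_path()
    if (!file.exists(cal_path)) {
      abort_invalid(sprintf(
        "cost-calibration file required but not found: %s", cal_path))
    }
    cal <- load_cost_calibration(cal_path)
  }

  rows <- map(raw$strategies, validate_strategy_entry, calibration = cal)
  strategies <- bind_rows(rows)
  if (anyDuplicated(strategies$name)) {
    abort_invalid("strategy names must be unique within an analysis.")
  }

  prov <- build_provenance(raw$provenance, cal, strategies$name)
  attr(strategies, "provenance") <- prov
  class(strategies) <- c("cea_strategies", class(strategies))

  structure(list(settings = settings, strategies = strategies),
            class = "cea_analysis")
}

validate_strategy_entry <- function(s, calibration = NULL) {
  all_fields <- c(STRATEGY_REQUIRED, STRATEGY_OPTIONAL)
  unknown <- setdiff(names(s), all_fields)
  if (length(unknown)) {
    abort_invalid(paste0("unknown strategy field(s) for '",
                         s$name %||% "?", "': ",
                         paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(STRATEGY_REQUIRED, names(s))
  if (length(missing)) {
    abort_invalid(paste0("strategy '", s$name %||% "?",
                         "' is missing required field(s): ",
                         paste(missing, collapse = ", ")))
  }

  # fill calibrated cost cells
  for (f in CALIBRATED_FIELDS) {
    if (is.null(s[[f]])) {
      if (is.null(calibration)) {
        abort_invalid(paste0("strategy '", s$name, "' omits `", f,
                             "` and no calibration is available."))
      }
      s[[f]] <- calibration_value(calibration, f, s)
    }
  }
  if (is.null(s$ae_profile)) {
    if (is.null(calibration)) {
      abort_invalid(paste0("strategy '", s$name,
                           "' omits `ae_profile` and no calibration is available."))
    }
    s$ae_profile <- calibration$ae_profiles[[s$biologic]]
    if (is.null(s$ae_profile)) {
      abort_invalid(paste0("no calibrated AE profile for arm '",
                           s$biologic, "'."))
    }
  } else if (!is_tibble(s$ae_profile)) {
    s$ae_profile <- bind_rows(map(s$ae_profile, as_tibble))
  }

  # invariants
  if (!s$biomarker_policy %in% c("KRAS_wt", "extended_RAS_wt")) {
    abort_invalid(paste0("strategy '", s$name, "': `biomarker_policy` must be ",
                         "'KRAS_wt' or 'extended_RAS_wt'."))
  }
  if (!s$biologic %in% c("Cetux", "Bev")) {
    abort_invalid(paste0("strategy '", s$name,
                         "': `biologic` must be 'Cetux' or 'Bev'."))
  }
  if (!s$backbone %in% c("FOLFOX", "FOLFIRI", "pooled")) {
    abort_invalid(paste0("strategy '", s$name,
                         "': `backbone` must be FOLFOX, FOLFIRI or pooled."))
  }
  assert_scalar_number(s$median_pfs_months, "median_pfs_months", min = 1e-9)
  assert_scalar_number(s$median_os_months, "median_os_months", min = 1e-9)
  if (s$median_os_months <= s$median_pfs_months) {
    abort_invalid(paste0(
      "strategy '", s$name, "': `median_os_months` must exceed ",
      "`median_pfs_months` (post-progression time must be positive)."))
  }
  assert_scalar_number(s$u_progressive, "u_progressive", min = 0, max = 1)
  assert_scalar_number(s$u_stable, "u_stable", min = s$u_progressive, max = 1)
  assert_scalar_number(s$bsa_m2, "bsa_m2", min = 1e-9)
  assert_scalar_number(s$body_weight_kg, "body_weight_kg", min = 1e-9)
  if (!s$biologic_schedule_days %in% c(7, 14) ||
      !s$backbone_schedule_days %in% c(7, 14)) {
    abort_invalid(paste0("strategy '", s$name,
                         "': schedules must be 7 or 14 days."))
  }
  has_bsa <- is_set(s$biologic_dose_per_bsa_mg_m2)
  has_kg <- is_set(s$biologic_dose_per_kg_mg_kg)
  if (has_bsa == has_kg) {
    abort_invalid(paste0("strategy '", s$name, "': exactly one of ",
                         "`biologic_dose_per_bsa_mg_m2` / ",
                         "`biologic_dose_per_kg_mg_kg` must be set."))
  }
  for (f in c("travel_cost_per_visit_usd", "absenteeism_cost_per_day_usd",
              "absenteeism_days_per_visit", CALIBRATED_FIELDS)) {
    assert_scalar_number(s[[f]], f, min = 0)
  }
  assert_scalar_number(s$ae_duration_months, "ae_duration_months", min = 1e-9)

  tibble(
    name = s$name,
    biomarker_policy = s$biomarker_policy,
    biologic = s$biologic,
    backbone = s$backbone,
    median_pfs_months = as.numeric(s$median_pfs_months),
    median_os_months = as.numeric(s$median_os_months),
    u_stable = as.numeric(s$u_stable),
    u_progressive = as.numeric(s$u_progressive),
    bsa_m2 = as.numeric(s$bsa_m2),
    body_weight_kg = as.numeric(s$body_weight_kg),
    biologic_dose_per_bsa_mg_m2 =
      if (has_bsa) as.numeric(s$biologic_dose_per_bsa_mg_m2) else NA_real_,
    biologic_dose_per_kg_mg_kg =
      if (has_kg) as.numeric(s$biologic_dose_per_kg_mg_kg) else NA_real_,
    biologic_loading_dose_per_bsa_mg_m2 =
      if (is_set(s$biologic_loading_dose_per_bsa_mg_m2))
        as.numeric(s$biologic_loading_dose_per_bsa_mg_m2) else NA_real_,
    biologic_schedule_days = as.numeric(s$biologic_schedule_days),
    backbone_schedule_days = as.numeric(s$backbone_schedule_days),
    biologic_unit_price_usd_per_mg =
      as.numeric(s$biologic_unit_price_usd_per_mg),
    backbone_cost_per_admin_usd = as.numeric(s$backbone_cost_per_admin_usd),
    admin_monitoring_cost_per_cycle_usd =
      as.numeric(s$admin_monitoring_cost_per_cycle_usd),
    progression_cost_per_month_usd =
      as.numeric(s$progression_cost_per_month_usd),
    travel_cost_per_visit_usd = as.numeric(s$travel_cost_per_visit_usd),
    absenteeism_cost_per_day_usd = as.numeric(s$absenteeism_cost_per_day_usd),
    absenteeism_days_per_visit = as.numeric(s$absenteeism_days_per_visit),
    ae_duration_months = as.numeric(s$ae_duration_months),
    ae_profile = list(as_tibble(s$ae_profile)))
}

calibration_value <- function(cal, field, s) {
  # arm-/backbone-specific items carry a ".<key>" suffix
  key <- switch(field,
                biologic_unit_price_usd_per_mg =
                  paste0("unit_price_usd_per_mg.", s$biologic),
                backbone_cost_per_admin_usd =
                  paste0("backbone_cost_per_admin_usd.", s$backbone),
                ae_duration_months =
                  paste0("ae_duration_months.", s$biologic),
                field)
  row <- cal$items[cal$items$item == key, ]
  if (nrow(row) != 1L) {
    abort_invalid(sprintf(
      "calibration item '%s' (for field `%s`) not found in %s.",
      key, field, cal$path))
  }
  row$value
}

#' Load the cost-calibration file
#'
#' The calibration file supplies cost cells that were not individually
#' published: drug unit prices derived from published per-administration
#' costs, backbone chemotherapy per-administration costs,
#' monitoring/administration and weighted subsequent-therapy costs, the
#' adverse-event profiles per biologic arm, and the implied on-treatment
#' durations. Every item carries a `status` (`published`, `derived` or
#' `assumed`) and a provenance `note`.
#'
#' @param path Path to the calibration YAML; defaults to the file shipped
#'   with the package.
#' @return List with `items` (tibble: item, value, status, note),
#'   `ae_profiles` (named list of tibbles, one per biologic arm) and the
#'   source `path`.
#' @export
load_cost_calibration <- function(path = default_calibration_path()) {
  if (!file.exists(path)) {
    abort_invalid(sprintf("cost-calibration file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("items", "ae_profiles"))
  if (length(unknown)) {
    abort_invalid(paste0("unknown calibration key(s): ",
                         paste(unknown, collapse = ", ")))
  }
  items <- imap(raw$items, function(x, nm) {
    bad <- setdiff(names(x), c("value", "status", "note"))
    if (length(bad)) {
      abort_invalid(paste0("calibration item '", nm, "' has unknown key(s): ",
                           paste(bad, collapse = ", ")))
    }
    tibble(item = nm, value = as.numeric(x$value),
           status = x$status %||% "assumed", note = x$note %||% "")
  })
  items <- bind_rows(items)
  if (any(!items$status %in% c("published", "derived", "assumed"))) {
    abort_invalid("calibration status must be published, derived or assumed.")
  }
  if (any(items$value < 0)) abort_invalid("calibration values must be >= 0.")
  ae_profiles <- map(raw$ae_profiles, function(arm) {
    tbl <- bind_rows(map(arm, as_tibble))
    req <- c("event", "incidence", "unit_cost_usd", "status")
    if (!all(req %in% names(tbl))) {
      abort_invalid("AE profile entries need event/incidence/unit_cost_usd/status.")
    }
    tbl
  })
  list(items = items, ae_profiles = ae_profiles, path = path)
}

default_calibration_path <- function() {
  system.file("extdata", "cost_calibration.yaml", package = "markovcea",
              mustWork = FALSE)
}

build_provenance <- function(prov_raw, cal, strategy_names) {
  rows <- map(prov_raw %||% list(), function(p) {
    tibble(field = p$field %||% "", status = p$status %||% "assumed",
           note = p$note %||% "")
  })
  prov <- bind_rows(rows)
  if (!is.null(cal)) {
    prov <- bind_rows(
      prov,
      cal$items |> select(field = "item", "status", "note"),
      tibble(field = "ae_profile",
             status = "derived",
             note = "incidences from CALGB 80405 trial report; unit costs calibrated"))
  }
  prov
}

#' Base-case analysis fixtures
#'
#' Returns the two analyses of the published base case, fully populated:
#' analysis 1 compares biomarker-testing policies (KRAS wild-type vs
#' extended RAS wild-type) crossed with Cetuximab/Bevacizumab on a pooled
#' chemotherapy backbone; analysis 2 compares FOLFOX vs FOLFIRI backbones
#' crossed with the two biologics in the extended RAS wild-type
#' population. Median survival, utilities, discounting and adverse-event
#' incidences are the published values; unpublished cost cells come from
#' the editable calibration file (see [load_cost_calibration()]).
#'
#' @param analysis 1 or 2.
#' @return A `cea_analysis` list; see [load_analysis_config()].
#' @examples
#' a1 <- base_case_analysis(1)
#' a1$strategies$name
#' @export
base_case_analysis <- function(analysis = 1) {
  if (!length(analysis) == 1L || !analysis %in% c(1, 2)) {
    abort_invalid("`analysis` must be 1 or 2.")
  }
  path <- system.file("extdata", sprintf("analysis%d.yaml", analysis),
                      package = "markovcea", mustWork = TRUE)
  load_analysis_config(path)
}

#' Published base-case totals
#'
#' The published per-strategy discounted totals (cost in USD, effectiveness
#' in QALYs) of the base case. These totals are themselves model inputs for
#' the ratio, dominance and willingness-to-pay arithmetic: the cohort
#' engine recomputes totals from first principles, but the published
#' unit-cost tables and accrual conventions are not fully recoverable, so
#' ratio reproduction starts from these published figures.
#'
#' @param analysis 1, 2 or `NULL` (both).
#' @return Tibble with columns `analysis`, `name`, `total_cost_usd`,
#'   `total_qaly`, `status`.
#' @export
base_case_totals <- function(analysis = NULL) {
  path <- system.file("extdata", "base_case_totals.csv",
                      package = "markovcea", mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = "icddc")
  if (!is.null(analysis)) tbl <- tbl[tbl$analysis == analysis, ]
  tbl
}

#' Retrieve field-level provenance of an analysis
#'
#' @param x A `cea_analysis` (or its `strategies` tibble).
#' @return Tibble with columns `field`, `status`, `note`.
#' @export
fixture_provenance <- function(x) {
  if (inherits(x, "cea_analysis")) x <- x$strategies
  attr(x, "provenance") %||% tibble(field = character(), status = character(),
                                    note = character())
}

#' Serialise an analysis back to YAML
#'
#' Writes a fully-resolved configuration (all calibrated cells inlined, AE
#' profiles included) so that reloading it with [load_analysis_config()]
#' reproduces identical parameter values without a calibration file.
#'
#' @param analysis A `cea_analysis` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(analysis, path) {
  stopifnot(inherits(analysis, "cea_analysis"))
  st <- analysis$strategies
  strategies <- map(seq_len(nrow(st)), function(i) {
    row <- as.list(st[i, ])
    row <- lapply(row, function(x) if (is.list(x)) x[[1]] else x)
    out <- list()
    for (f in setdiff(names(st), "ae_profile")) {
      v <- row[[f]]
      if (length(v) == 1L && is.na(v)) next
      out[[f]] <- if (is.numeric(v)) as.numeric(v) else v
    }
    prof <- row$ae_profile
    out$ae_profile <- map(seq_len(nrow(prof)), function(j) as.list(prof[j, ]))
    out
  })
  settings <- analysis$settings
  attributes(settings) <- list(names = names(settings))
  yaml::write_yaml(list(settings = settings, strategies = strategies), path,
                   precision = 15)
  invisible(path)
}

#' @export
print.cea_analysis <- function(x, ...) {
  cat(sprintf("CEA analysis: %d strategies\n", nrow(x$strategies)))
  print(select(as_tibble(x$strategies), "name", "biomarker_policy",
               "biologic", "backbone", "median_pfs_months",
               "median_os_months"))
  invisible(x)
}
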