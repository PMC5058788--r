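test_that("base-case fixtures carry the published survival and utility inputs", {
  st1 <- analysis1$strategies
  expect_setequal(st1$name, c("KRAS-Cetux", "KRAS-Bev", "RAS-Cetux", "RAS-Bev"))
  ras_bev <- st1[st1$name == "RAS-Bev", ]
  expect_equal(ras_bev$median_os_months, 31.2)
  expect_equal(ras_bev$median_pfs_months, 11.3)
  expect_equal(st1$u_stable, rep(0.85, 4))
  expect_equal(st1$u_progressive, rep(0.65, 4))
  expect_equal(analysis1$settings$annual_discount_rate, 0.03)
  expect_equal(analysis1$settings$currency_rate_cny_per_usd, 6.15)

  st2 <- analysis2$strategies
  expect_setequal(st2$name, c("FOLFOX-Cetux", "FOLFOX-Bev",
                              "FOLFIRI-Cetux", "FOLFIRI-Bev"))
  fb <- st2[st2$name == "FOLFIRI-Bev", ]
  expect_equal(fb$backbone, "FOLFIRI")
  expect_equal(fb$biologic, "Bev")

  expect_error(base_case_analysis(3), class = "markovcea_invalid")
})

test_that("config validation rejects broken inputs by name", {
  path <- system.file("extdata", "analysis1.yaml", package = "markovcea")
  raw <- yaml::read_yaml(path)

  # boundary of the survival invariant: OS equal to PFS
  bad <- raw
  bad$strategies[[1]]$median_os_months <- bad$strategies[[1]]$median_pfs_months
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(load_analysis_config(f), "median_os_months",
               class = "markovcea_invalid")

  # missing required field named in the error
  bad <- raw
  bad$strategies[[2]]$u_stable <- NULL
  yaml::write_yaml(bad, f)
  expect_error(load_analysis_config(f), "u_stable",
               class = "markovcea_invalid")

  # unknown keys rejected
  bad <- raw
  bad$strategies[[1]]$mystery_knob <- 1
  yaml::write_yaml(bad, f)
  expect_error(load_analysis_config(f), "mystery_knob",
               class = "markovcea_invalid")

  # both dose fields set
  bad <- raw
  bad$strategies[[1]]$biologic_dose_per_kg_mg_kg <- 5
  yaml::write_yaml(bad, f)
  expect_error(load_analysis_config(f), "exactly one",
               class = "markovcea_invalid")

  # duplicated strategy names
  bad <- raw
  bad$strategies[[2]]$name <- bad$strategies[[1]]$name
  yaml::write_yaml(bad, f)
  expect_error(load_analysis_config(f), "unique",
               class = "markovcea_invalid")
})

test_that("a missing calibration file is reported by path", {
  path <- system.file("extdata", "analysis1.yaml", package = "markovcea")
  expect_error(load_analysis_config(path, calibration = "/nonexistent/cal.yaml"),
               "/nonexistent/cal.yaml", class = "markovcea_invalid")
})

test_that("configs round-trip through serialisation with identical values", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_analysis_config(analysis1, f)
  back <- load_analysis_config(f)
  expect_equal(back$settings, analysis1$settings)
  num_cols <- names(analysis1$strategies)[vapply(analysis1$strategies,
                                                 is.numeric, TRUE)]
  for (cl in num_cols) {
    expect_equal(back$strategies[[cl]], analysis1$strategies[[cl]],
                 tolerance = 1e-12, label = cl)
  }
  expect_equal(back$strategies$name, analysis1$strategies$name)
  for (i in seq_len(nrow(back$strategies))) {
    expect_equal(back$strategies$ae_profile[[i]]$incidence,
                 analysis1$strategies$ae_profile[[i]]$incidence)
    expect_equal(back$strategies$ae_profile[[i]]$unit_cost_usd,
                 analysis1$strategies$ae_profile[[i]]$unit_cost_usd)
  }
})

test_that("every fixture field carries retrievable provenance", {
  prov <- fixture_provenance(analysis1)
  expect_true(all(c("field", "status", "note") %in% names(prov)))
  expect_true(all(prov$status %in% c("published", "derived", "assumed")))
  # survival, utility, dosing, societal and calibrated cost fields covered
  for (f in c("median_pfs_months", "median_os_months", "u_stable",
              "u_progressive", "bsa_m2", "body_weight_kg",
              "travel_cost_per_visit_usd", "absenteeism_cost_per_day_usd")) {
    expect_true(f %in% prov$field, label = f)
  }
  expect_true(any(grepl("unit_price", prov$field)))
  expect_true(any(grepl("ae_duration", prov$field)))
  # analysis 2 marks the reused pooled PFS as assumed
  prov2 <- fixture_provenance(analysis2)
  expect_equal(prov2$status[prov2$field == "median_pfs_months"], "assumed")
})

test_that("calibration items are typed and statused", {
  cal <- load_cost_calibration()
  expect_true(all(cal$items$status %in% c("published", "derived", "assumed")))
  expect_true(all(cal$items$value >= 0))
  expect_setequal(names(cal$ae_profiles), c("Cetux", "Bev"))
  expect_true(all(cal$ae_profiles$Cetux$incidence >= 0 &
                    cal$ae_profiles$Cetux$incidence <= 1))
})
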