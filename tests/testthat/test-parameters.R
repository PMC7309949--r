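test_that("packaged defaults reproduce the calibrated base case", {
  p <- base_params
  # clinical
  expect_equal(p$clinical$responder_fraction, 0.60)
  expect_equal(p$clinical$nonresponder_withdrawal_per_cycle, 0.60)
  expect_equal(p$clinical$nbds_baseline, 16.74)
  expect_equal(p$clinical$nbds_delta_responder, -6)
  expect_equal(p$clinical$nbds_delta_nonresponder, 1)
  expect_equal(p$clinical$uti_rate_sbc_per_cycle, 0.512)
  expect_equal(p$clinical$uti_rate_tai_per_cycle, 0.195)
  expect_equal(p$clinical$hosp_decubitus_sbc, 0.31)
  expect_equal(p$clinical$hosp_decubitus_tai, 0.14)
  expect_equal(p$clinical$hosp_other_sbc, 1.73)
  expect_equal(p$clinical$hosp_other_tai, 0.77)
  expect_equal(p$clinical$nursing_rate_sbc, 0.318)
  expect_equal(p$clinical$nursing_rate_tai, 0.1941)
  expect_equal(p$clinical$nursing_visits_per_week, 2)
  expect_equal(p$clinical$stoma_rate_per_cycle, 0.00033)
  expect_equal(p$clinical$laparoscopic_fraction, 0.575)
  expect_equal(unlist(p$clinical$uti_treatment_split),
               c(hospitalized = 0.086, outpatient = 0.811, untreated = 0.103))
  # utility
  expect_equal(p$utility$u_responder, 0.533)
  expect_equal(p$utility$u_nonresponder, 0.470)
  expect_equal(p$utility$u_sbc, 0.479)
  expect_equal(p$utility$u_stoma, 0.564)
  expect_equal(p$utility$du_uti_per_event, 0.060)
  expect_equal(p$utility$du_hosp_per_event, 0.010)
  # cost
  expect_equal(p$cost$device_cost_per_year, 280945)
  expect_equal(p$cost$sbc_cost_per_month, 4151)
  expect_equal(p$cost$stoma_fee_laparoscopic, 139200)
  expect_equal(p$cost$stoma_fee_open, 79800)
  expect_equal(p$cost$stoma_hosp_laparoscopic, 236311)
  expect_equal(p$cost$stoma_hosp_open, 242686)
  expect_equal(p$cost$stoma_mgmt_month_y1, 4131)
  expect_equal(p$cost$stoma_mgmt_month_after, 1621)
  expect_equal(p$cost$uti_cost_hospitalized, 163113)
  expect_equal(p$cost$uti_cost_outpatient, 14126)
  expect_equal(p$cost$uti_cost_untreated, 10293)
  expect_equal(p$cost$nursing_cost_per_visit, 5800)
  expect_equal(p$cost$nursing_premium_per_week, 5200)
  expect_equal(p$cost$hosp_cost_decubitus, 1512630)
  expect_equal(p$cost$hosp_cost_other, 630960)
  # productivity
  expect_equal(p$productivity$employment_rate, 0.488)
  expect_equal(unlist(p$productivity$absenteeism),
               c(minor = 0, moderate = 0.0221, severe = 0.0701))
  expect_equal(unlist(p$productivity$presenteeism),
               c(minor = 0.17, moderate = 0.3636, severe = 0.3971))
  expect_equal(unlist(p$productivity$wage_per_month),
               c(age_50_54 = 364163, age_55_59 = 350789, age_60_64 = 262659,
                 age_65_69 = 244283, age_70_plus = 248227))
  # settings
  expect_equal(p$settings$cycle_length_years, 0.5)
  expect_equal(p$settings$annual_discount_rate, 0.02)
  expect_equal(p$settings$start_age, 51.46)
  expect_equal(p$settings$male_fraction, 0.783)
  expect_equal(p$settings$tai_procedure_fee_per_month, 18000)
})

test_that("overrides pass through and invalid configurations are rejected by field", {
  p <- load_parameters(overrides = list(settings = list(annual_discount_rate = 0)))
  expect_equal(p$settings$annual_discount_rate, 0)
  expect_equal(p$clinical$uti_rate_sbc_per_cycle, 0.512)  # untouched default

  expect_error(
    load_parameters(overrides = list(clinical = list(uti_treatment_split = list(
      hospitalized = 0.086, outpatient = 0.711, untreated = 0.103)))),
    "uti_treatment_split", class = "nbdcea_validation_error")
  expect_error(
    load_parameters(overrides = list(cost = list(sbc_cost_per_month = -1))),
    "cost.sbc_cost_per_month", class = "nbdcea_validation_error")
  expect_error(
    load_parameters(overrides = list(clinical = list(uti_rate_sbc_per_cycle = 1.4))),
    "uti_rate_sbc_per_cycle", class = "nbdcea_validation_error")
  expect_error(
    load_parameters(overrides = list(settings = list(annual_discount_rate = 1))),
    "annual_discount_rate", class = "nbdcea_validation_error")
  expect_error(
    load_parameters(overrides = list(settings = list(perspective = "martian"))),
    "perspective", class = "nbdcea_validation_error")
})

test_that("config round-trip through YAML is the identity on the parameter set", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  blocks <- base_params[c("settings", "clinical", "utility", "cost", "productivity")]
  yaml::write_yaml(blocks, tmp)
  p2 <- load_parameters(config = tmp)
  expect_equal(p2[c("settings", "clinical", "utility", "cost", "productivity")],
               blocks, tolerance = 1e-12)
})

test_that("derived cost quantities follow from the fee-schedule components", {
  dc <- derived_costs(base_params)
  expect_equal(dc$system_cost_per_year, 24190)
  expect_equal(dc$device_cost_per_year, 280945)
  expect_equal(dc$stoma_surgery_fee, 113955)
  expect_equal(round(dc$stoma_surgery_hospitalization), 239020)
  expect_equal(dc$weekly_nursing_cost, 2 * 5800 + 5200)
  expect_equal(dc$uti_episode_cost,
               0.086 * 163113 + 0.811 * 14126 + 0.103 * 10293)
})

test_that("parameter registry flags beta for bounded and gamma for unbounded inputs", {
  reg <- parameter_registry(base_params)
  expect_true(all(reg$value[reg$family == "beta"] >= 0 &
                    reg$value[reg$family == "beta"] <= 1))
  expect_true(all(reg$family[grepl("^cost\\.", reg$path)] == "gamma"))
  expect_contains(reg$path[reg$family == "gamma"], "clinical.hosp_other_sbc")
  # round-trip of path access
  for (i in seq_len(nrow(reg))) {
    expect_equal(as.numeric(param_get(base_params, reg$path[i])), reg$value[i])
  }
  p2 <- param_set(base_params, "utility.u_sbc", 0.3)
  expect_equal(p2$utility$u_sbc, 0.3)
  expect_equal(base_params$utility$u_sbc, 0.479)  # original untouched
})
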