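test_that("discount factor follows annual compound discounting", {
  expect_identical(discount_factor(0, 0.02), 1)
  expect_equal(discount_factor(1, 0.02), 1 / 1.02)
  expect_equal(discount_factor(0.5, 0.02), 1.02^-0.5)
  expect_identical(discount_factor(5, 0), 1)
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("transition matrix rows encode withdrawal, stoma and death competing risks", {
  states <- health_states()
  m0 <- build_transition_matrix(base_params, "TAI", age = 60, q_death = 0)
  expect_equal(unname(m0["TAI_NONRESPONDER", ]), c(0, 0.40, 0.60, 0, 0, 0))
  expect_equal(m0["SBC", "STOMA"], 0.00033)
  expect_equal(m0["SBC", "SBC"], 0.99967)
  expect_equal(unname(m0["TAI_RESPONDER", ]), c(1, 0, 0, 0, 0, 0))

  m1 <- build_transition_matrix(base_params, "SBC", age = 60, q_death = 1)
  expect_equal(unname(m1[, "DEAD"]), rep(1, 6))
  expect_true(all(m1[, setdiff(states, "DEAD")] == 0))

  mq <- build_transition_matrix(base_params, "TAI", age = 80, q_death = 0.1)
  expect_equal(rowSums(mq), setNames(rep(1, 6), states), tolerance = 1e-15)
  expect_equal(mq["TAI_NONRESPONDER", "RESUME_SBC"], 0.60 * 0.9)
  expect_true(all(diff(c(0, mq["DEAD", "DEAD"])) >= 0))

  mi <- build_transition_matrix(
    nbd_parameters(settings = list(withdrawal_mode = "immediate")),
    "TAI", age = 60, q_death = 0)
  expect_equal(mi["TAI_NONRESPONDER", "RESUME_SBC"], 1)
})

test_that("cohort start vectors, one-step occupancy and conservation hold", {
  tr_sbc <- run_cohort(base_params, "SBC")
  expect_equal(unname(attr(tr_sbc, "initial")), c(0, 0, 0, 1, 0, 0))
  tr_tai <- run_cohort(base_params, "TAI")
  expect_equal(unname(attr(tr_tai, "initial")), c(0.6, 0.4, 0, 0, 0, 0))

  # one matrix application by hand under zero mortality
  p0 <- zero_mortality_params()
  tr0 <- run_cohort(p0, "TAI")
  expect_equal(tr0$TAI_NONRESPONDER[1], 0.4 * 0.4)
  expect_equal(tr0$TAI_NONRESPONDER[2], 0.4 * 0.4 * 0.4)
  expect_equal(tr0$RESUME_SBC[1], 0.4 * 0.6)

  # occupancy conservation and monotone death, every cycle, both arms
  for (tr in list(tr_sbc, tr_tai)) {
    occ <- as.matrix(as.data.frame(tr)[, health_states()])
    expect_true(all(abs(rowSums(occ) - 1) <= 1e-12))
    expect_true(all(occ >= 0 & occ <= 1))
    expect_true(all(diff(tr$DEAD) >= -1e-15))
  }
})

test_that("zero-discount zero-mortality SBC QALYs match the closed form", {
  p <- zero_mortality_params(
    settings = list(annual_discount_rate = 0),
    clinical = list(stoma_rate_per_cycle = 0))
  tr <- run_cohort(p, "SBC")
  n <- nrow(tr)
  per_cycle <- 0.479 * 0.5 - 0.512 * 0.060 -
    (0.31 + 1.73) * (0.5 / 8.5) * 0.010
  expect_equal(sum(tr$disc_qaly), n * per_cycle, tolerance = 1e-12)
  expect_equal(sum(tr$qaly), sum(tr$disc_qaly))
})

test_that("a 3-cycle model matches a spreadsheet-style hand oracle to 1e-9", {
  q_annual <- 0.04
  p <- nbd_parameters(settings = list(start_age = 108.5),
                      lifetable = flat_lifetable(q_annual))
  tr <- run_cohort(p, "TAI")
  expect_equal(nrow(tr), 3L)

  # --- independent oracle: explicit scalar arithmetic from the table values
  q <- 1 - (1 - q_annual)^0.5          # per-cycle death probability
  uti_cost <- 0.086 * 163113 + 0.811 * 14126 + 0.103 * 10293
  week_nurse <- 2 * 5800 + 5200
  per_cyc_h <- 0.5 / 8.5
  cost_tai_state <- 280945 / 2 + 18000 * 6 +
    0.195 * uti_cost + 0.14 * per_cyc_h * 1512630 + 0.77 * per_cyc_h * 630960 +
    0.1941 * week_nurse * 26
  cost_sbc_state <- 4151 * 6 +
    0.512 * uti_cost + 0.31 * per_cyc_h * 1512630 + 1.73 * per_cyc_h * 630960 +
    0.318 * week_nurse * 26
  cost_stoma_y1 <- 4131 * 6 +
    0.512 * uti_cost + 0.31 * per_cyc_h * 1512630 + 1.73 * per_cyc_h * 630960 +
    0.318 * week_nurse * 26
  stoma_oneoff <- (0.575 * 139200 + 0.425 * 79800) +
    (0.575 * 236311 + 0.425 * 242686)
  q_tai_r <- 0.533 * 0.5 - 0.195 * 0.06 - (0.14 + 0.77) * per_cyc_h * 0.01
  q_tai_n <- 0.470 * 0.5 - 0.195 * 0.06 - (0.14 + 0.77) * per_cyc_h * 0.01
  q_sbc  <- 0.479 * 0.5 - 0.512 * 0.06 - (0.31 + 1.73) * per_cyc_h * 0.01
  q_stoma <- 0.564 * 0.5 - 0.512 * 0.06 - (0.31 + 1.73) * per_cyc_h * 0.01

  st <- 0.00033
  occ <- c(r = 0.6, n = 0.4, rs = 0, stoma = 0)
  total_cost <- 0; total_qaly <- 0
  stoma_mass <- numeric(0)
  for (t in 1:3) {
    inflow <- occ[["rs"]] * st * (1 - q)
    occ_new <- c(
      r = occ[["r"]] * (1 - q),
      n = occ[["n"]] * 0.4 * (1 - q),
      rs = occ[["n"]] * 0.6 * (1 - q) + occ[["rs"]] * (1 - st) * (1 - q),
      stoma = occ[["stoma"]] * (1 - q) + inflow)
    stoma_mass <- c(stoma_mass * (1 - q), inflow)
    n_e <- length(stoma_mass)
    mass_y1 <- sum(stoma_mass[max(1, n_e - 1):n_e])    # entry + following cycle
    mass_late <- sum(stoma_mass) - mass_y1
    c_t <- (occ_new[["r"]] + occ_new[["n"]]) * cost_tai_state +
      occ_new[["rs"]] * cost_sbc_state +
      mass_y1 * cost_stoma_y1 +
      mass_late * (cost_stoma_y1 - (4131 - 1621) * 6) +
      inflow * stoma_oneoff
    q_t <- occ_new[["r"]] * q_tai_r + occ_new[["n"]] * q_tai_n +
      occ_new[["rs"]] * q_sbc + occ_new[["stoma"]] * q_stoma
    d <- 1.02^(-t * 0.5)
    total_cost <- total_cost + c_t * d
    total_qaly <- total_qaly + q_t * d
    occ <- occ_new
  }
  expect_equal(sum(tr$disc_cost), total_cost, tolerance = 1e-9)
  expect_equal(sum(tr$disc_qaly), total_qaly, tolerance = 1e-9)
})

test_that("per-state accruals include stoma tenure and event decrements", {
  expect_equal(accrue_cycle_qaly("STOMA",
                                 nbd_parameters(settings = list(stoma_events_mode = "management_only"))),
               0.564 * 0.5)
  expect_equal(accrue_cycle_cost("TAI_RESPONDER", base_params) -
                 accrue_cycle_cost("TAI_NONRESPONDER", base_params), 0)
  y1 <- accrue_cycle_cost("STOMA", base_params, time_in_stoma = 0.5)
  late <- accrue_cycle_cost("STOMA", base_params, time_in_stoma = 2)
  expect_equal(y1 - late, (4131 - 1621) * 6)
  expect_identical(accrue_cycle_cost("DEAD", base_params), 0)
  expect_identical(accrue_cycle_qaly("DEAD", base_params), 0)
})

test_that("raising costs raises arm cost and raising utilities raises arm QALYs", {
  base <- glance(run_base_case(base_params))
  for (pth in c("cost.sbc_cost_per_month", "cost.hosp_cost_other",
                "cost.uti_cost_outpatient", "cost.nursing_cost_per_visit")) {
    up <- glance(run_base_case(param_set(base_params, pth,
                                         1.5 * param_get(base_params, pth))))
    expect_gte(up$cost_sbc, base$cost_sbc)
    expect_gte(up$cost_tai, base$cost_tai)
  }
  for (pth in c("utility.u_sbc", "utility.u_responder", "utility.u_stoma")) {
    up <- glance(run_base_case(param_set(base_params, pth,
                                         param_get(base_params, pth) + 0.05)))
    expect_gte(up$qaly_sbc, base$qaly_sbc)
    expect_gte(up$qaly_tai, base$qaly_tai)
  }
})

test_that("ICER handles ratios, dominance, indifference and undefined cases", {
  r <- compute_icer(3198687, 0.80)
  expect_equal(r$icer, 3198687 / 0.80)
  expect_equal(r$status, "ratio")
  expect_equal(compute_icer(-522293, 0.80)$status, "dominant")
  expect_equal(compute_icer(100, -0.1)$status, "dominated")
  expect_equal(compute_icer(0, 0)$status, "indifferent")
  expect_equal(compute_icer(100, 0)$status, "undefined")
  expect_true(is.na(compute_icer(100, 0)$icer))
  expect_equal(compute_icer(-100, 0)$status, "dominant")
})

test_that("TAI arm gains QALYs over SBC under the base calibration", {
  g <- glance(run_base_case(base_params))
  expect_gt(g$qaly_tai, g$qaly_sbc)
})

test_that("half-cycle correction changes accruals only modestly and keeps signs", {
  g0 <- glance(run_base_case(base_params))
  g1 <- glance(run_base_case(nbd_parameters(settings = list(half_cycle_correction = TRUE))))
  expect_gt(g1$qaly_tai, g0$qaly_tai)  # start-of-cycle mass now counts
  expect_lt(abs(g1$icer - g0$icer) / g0$icer, 0.1)
  expect_equal(g1$icer_status, "ratio")
})
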