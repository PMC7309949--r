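#' Health states of the cohort model
#'
#' Six states: TAI responders (satisfactory bowel management on irrigation,
#' retained for life), TAI non-responders (still irrigating but without
#' benefit, withdrawing over time), non-responders who have resumed standard
#' bowel care, the standard-bowel-care comparator state, colostomy (absorbing
#' apart from death), and death.
#'
#' @return Character vector of the six state labels, in transition-matrix
#'   order.
#' @export
health_states <- function() {
  c("TAI_RESPONDER", "TAI_NONRESPONDER", "RESUME_SBC", "SBC", "STOMA", "DEAD")
}

#' Discount factor at a point in time
#'
#' Annual-rate compound discounting, `(1 + rate)^(-time_years)`, evaluated at
#' cycle end in the engine.
#'
#' @param time_years Non-negative time in years.
#' @param rate Annual discount rate as a fraction (e.g. 0.02).
#' @return Discount factor in (0, 1].
#' @export
#' @examples
#' discount_factor(1, 0.02)    # 1/1.02
#' discount_factor(0.5, 0.02)  # 1.02^-0.5
discount_factor <- function(time_years, rate) {
  if (any(rate < 0)) abort("discount rate must be non-negative")
  if (any(time_years < 0)) abort("time must be non-negative")
  (1 + rate)^(-time_years)
}

#' Build the one-cycle transition matrix
#'
#' Mortality is applied first: the age- and sex-mixed cycle death probability
#' `q` moves every state to Dead, and all competing transitions are scaled by
#' `1 - q`.  Conditional on survival: TAI responders persist; TAI
#' non-responders move to resumed standard care with the per-cycle withdrawal
#' probability (or certainty, under `withdrawal_mode = "immediate"`); the two
#' standard-care states undergo stoma construction with the per-cycle stoma
#' rate; the stoma state persists.
#'
#' @param params An `nbd_parameters` object.
#' @param arm `"TAI"` or `"SBC"` (the matrix is shared; the argument is kept
#'   for interface symmetry and validated).
#' @param age Age of the cohort at the start of the cycle, in years.
#' @param q_death Optional override of the cycle death probability (used in
#'   tests); computed from the life table when `NULL`.
#' @return A 6 x 6 row-stochastic matrix over [health_states()].
#' @export
build_transition_matrix <- function(params, arm = c("TAI", "SBC"), age,
                                    q_death = NULL) {
  arm <- match.arg(arm)
  s <- params$settings
  if (is.null(q_death))
    q_death <- cycle_death_prob(params$lifetable, age, s$male_fraction,
                                s$excess_mortality_smr, s$cycle_length_years)
  w <- if (s$withdrawal_mode == "immediate") 1 else
    params$clinical$nonresponder_withdrawal_per_cycle
  st <- params$clinical$stoma_rate_per_cycle
  p <- 1 - q_death
  states <- health_states()
  m <- matrix(0, 6, 6, dimnames = list(states, states))
  m["TAI_RESPONDER", ] <- c(p, 0, 0, 0, 0, q_death)
  m["TAI_NONRESPONDER", ] <- c(0, (1 - w) * p, w * p, 0, 0, q_death)
  m["RESUME_SBC", ] <- c(0, 0, (1 - st) * p, 0, st * p, q_death)
  m["SBC", ] <- c(0, 0, 0, (1 - st) * p, st * p, q_death)
  m["STOMA", ] <- c(0, 0, 0, 0, p, q_death)
  m["DEAD", ] <- c(0, 0, 0, 0, 0, 1)
  dev <- abs(rowSums(m) - 1)
  if (any(dev > 1e-12))
    abort(sprintf("transition matrix row sums deviate from 1 by up to %g", max(dev)))
  m
}

# Per-cycle event rates by state: hospitalization frequencies are survey
# recall totals ("times/patient") spread over the recall window and scaled
# to the cycle length.
state_event_rates <- function(params, state) {
  cl <- params$clinical
  per_cycle <- params$settings$cycle_length_years / cl$hospitalization_recall_years
  tai_like <- state %in% c("TAI_RESPONDER", "TAI_NONRESPONDER")
  sbc_like <- state %in% c("RESUME_SBC", "SBC") ||
    (state == "STOMA" && params$settings$stoma_events_mode == "sbc_rates")
  if (tai_like) {
    list(uti = cl$uti_rate_tai_per_cycle,
         hosp_dec = cl$hosp_decubitus_tai * per_cycle,
         hosp_oth = cl$hosp_other_tai * per_cycle,
         nursing = cl$nursing_rate_tai)
  } else if (sbc_like) {
    list(uti = cl$uti_rate_sbc_per_cycle,
         hosp_dec = cl$hosp_decubitus_sbc * per_cycle,
         hosp_oth = cl$hosp_other_sbc * per_cycle,
         nursing = cl$nursing_rate_sbc)
  } else {
    list(uti = 0, hosp_dec = 0, hosp_oth = 0, nursing = 0)
  }
}

#' Undiscounted cost accrued per person-cycle in a state
#'
#' TAI states accrue half the annual device cost plus six months of procedure
#' fee; standard-care states accrue six months of conservative bowel-care
#' cost; the stoma state accrues management costs at the first-year monthly
#' rate during the first year after construction and the maintenance rate
#' thereafter (surgery and its hospitalization are one-off entry costs
#' handled by the engine on the entry cycle, see [run_cohort()]).  Every
#' alive state adds expected event costs: UTI episodes at the
#' treatment-split-weighted episode cost, decubitus and other
#' hospitalizations at their unit costs, and visiting nursing at the weekly
#' cost for 26 weeks, all at arm-specific rates (the stoma state uses
#' standard-care rates unless `stoma_events_mode = "management_only"`).
#'
#' @param state One of [health_states()].
#' @param params An `nbd_parameters` object.
#' @param arm `"TAI"` or `"SBC"` (interface symmetry; costs are
#'   state-determined).
#' @param cycle_index Cycle number, 1-based (unused except for interface
#'   completeness).
#' @param time_in_stoma Years since stoma construction (determines the
#'   management rate); only used for the stoma state.
#' @return Cost in yen per person-cycle, undiscounted.
#' @export
accrue_cycle_cost <- function(state, params, arm = "TAI", cycle_index = 1L,
                              time_in_stoma = 0) {
  if (state == "DEAD") return(0)
  s <- params$settings
  co <- params$cost
  dc <- derived_costs(params)
  r <- state_event_rates(params, state)
  months <- s$cycle_length_years * 12
  weeks <- s$cycle_length_years * 52
  base <- switch(state,
    TAI_RESPONDER = ,
    TAI_NONRESPONDER = co$device_cost_per_year * s$cycle_length_years +
      s$tai_procedure_fee_per_month * months,
    RESUME_SBC = ,
    SBC = co$sbc_cost_per_month * months,
    STOMA = (if (time_in_stoma < 1) co$stoma_mgmt_month_y1 else co$stoma_mgmt_month_after) *
      months)
  events <- r$uti * dc$uti_episode_cost +
    r$hosp_dec * co$hosp_cost_decubitus +
    r$hosp_oth * co$hosp_cost_other +
    r$nursing * dc$weekly_nursing_cost * weeks
  total <- base + events
  if (total < 0) abort("negative cycle cost component")
  total
}

#' Undiscounted QALY accrued per person-cycle in a state
#'
#' The state utility weight times the cycle length, minus one-off additive
#' event disutilities: the UTI rate times the per-episode decrement and the
#' total hospitalization rate times the per-admission decrement.  The result
#' is floored at minus the cycle length (utility cannot fall below -1).
#'
#' @inheritParams accrue_cycle_cost
#' @return QALYs per person-cycle, undiscounted.
#' @export
accrue_cycle_qaly <- function(state, params, arm = "TAI") {
  if (state == "DEAD") return(0)
  u <- params$utility
  uw <- switch(state,
    TAI_RESPONDER = u$u_responder,
    TAI_NONRESPONDER = u$u_nonresponder,
    RESUME_SBC = ,
    SBC = u$u_sbc,
    STOMA = u$u_stoma)
  r <- state_event_rates(params, state)
  cl_years <- params$settings$cycle_length_years
  q <- uw * cl_years - r$uti * u$du_uti_per_event -
    (r$hosp_dec + r$hosp_oth) * u$du_hosp_per_event
  max(q, -cl_years)
}

#' Run the cohort through the Markov model
#'
#' Starts the TAI arm split 60/40 across responder/non-responder states (the
#' SBC arm entirely in standard care), iterates age-updated transition
#' matrices in half-year cycles until the cohort reaches the maximum age, and
#' accrues per-cycle costs and QALYs on end-of-cycle occupancy (or the
#' cycle-average occupancy under the half-cycle correction), discounted at
#' cycle end.  Stoma surgery and its hospitalization are charged to the
#' per-cycle inflow into the stoma state; stoma management costs follow each
#' entry cohort's tenure.  Under a societal perspective, productivity losses
#' are added to every alive state's cycle cost (see
#' [productivity_loss_per_cycle()]).
#'
#' @param params An `nbd_parameters` object.
#' @param arm `"TAI"` or `"SBC"`.
#' @return An object of class `nbd_trace`: a tibble with one row per cycle
#'   (columns `cycle`, `age`, the six state occupancies, `stoma_inflow`,
#'   `cost`, `qaly`, `disc_cost`, `disc_qaly`) carrying the arm label and
#'   totals as attributes.
#' @export
run_cohort <- function(params, arm = c("TAI", "SBC")) {
  arm <- match.arg(arm)
  s <- params$settings
  states <- health_states()
  n_cycles <- ceiling((s$max_age - s$start_age) / s$cycle_length_years)
  occ <- matrix(0, n_cycles + 1L, 6L, dimnames = list(NULL, states))
  occ[1L, ] <- if (arm == "TAI")
    c(params$clinical$responder_fraction, 1 - params$clinical$responder_fraction, 0, 0, 0, 0)
  else c(0, 0, 0, 1, 0, 0)

  # undiscounted per-person-cycle accruals by state (tenure-dependent for stoma)
  cost_state <- vapply(states, accrue_cycle_cost, numeric(1),
                       params = params, arm = arm)
  cost_stoma_late <- accrue_cycle_cost("STOMA", params, arm, time_in_stoma = 1.5)
  qaly_state <- vapply(states, accrue_cycle_qaly, numeric(1),
                       params = params, arm = arm)
  dc <- derived_costs(params)
  stoma_oneoff <- dc$stoma_surgery_fee + dc$stoma_surgery_hospitalization
  first_year_cycles <- max(1L, ceiling(1 / s$cycle_length_years))

  societal <- s$perspective != "payer"
  if (societal) {
    mode <- if (s$perspective == "societal_full") "absenteeism_plus_presenteeism" else "absenteeism"
    state_nbds <- state_nbds_scores(params)
  }

  inflow <- numeric(n_cycles)
  cost <- numeric(n_cycles); qaly <- numeric(n_cycles)
  ages <- s$start_age + (seq_len(n_cycles) - 1L) * s$cycle_length_years
  q_death <- cycle_death_prob(params$lifetable, ages, s$male_fraction,
                              s$excess_mortality_smr, s$cycle_length_years)
  stoma_by_entry <- numeric(0)  # surviving mass by entry cycle (oldest first)

  for (t in seq_len(n_cycles)) {
    m <- build_transition_matrix(params, arm, ages[t], q_death = q_death[t])
    prev <- occ[t, ]
    cur <- setNames(as.numeric(prev %*% m), states)
    occ[t + 1L, ] <- cur
    inflow[t] <- (prev[["RESUME_SBC"]] + prev[["SBC"]]) *
      params$clinical$stoma_rate_per_cycle * (1 - q_death[t])
    stoma_by_entry <- c(stoma_by_entry * (1 - q_death[t]), inflow[t])
    n_entries <- length(stoma_by_entry)
    recent <- seq.int(max(1L, n_entries - first_year_cycles + 1L), n_entries)
    stoma_y1 <- sum(stoma_by_entry[recent])
    stoma_later <- sum(stoma_by_entry) - stoma_y1

    w <- if (isTRUE(s$half_cycle_correction)) (prev + cur) / 2 else cur
    alive <- setdiff(states, "DEAD")
    c_t <- sum(w[alive[alive != "STOMA"]] * cost_state[alive[alive != "STOMA"]]) +
      stoma_y1 * cost_state[["STOMA"]] + stoma_later * cost_stoma_late +
      inflow[t] * stoma_oneoff
    q_t <- sum(w[alive] * qaly_state[alive])
    if (societal) {
      age_mid <- ages[t] + s$cycle_length_years / 2
      loss <- vapply(alive, function(st)
        productivity_loss_per_cycle(age_mid, nbds_category(state_nbds[[st]]),
                                    params$productivity, mode = mode,
                                    cycle_years = s$cycle_length_years),
        numeric(1))
      c_t <- c_t + sum(w[alive] * loss)
    }
    cost[t] <- c_t
    qaly[t] <- q_t
  }

  disc <- discount_factor(seq_len(n_cycles) * s$cycle_length_years,
                          s$annual_discount_rate)
  trace <- tibble(cycle = seq_len(n_cycles),
                  age = ages + s$cycle_length_years) %>%
    dplyr::bind_cols(as_tibble(occ[-1L, , drop = FALSE])) %>%
    mutate(stoma_inflow = inflow, cost = cost, qaly = qaly,
           disc_cost = cost * disc, disc_qaly = qaly * disc)
  structure(trace, class = c("nbd_trace", class(trace)),
            arm = arm, initial = occ[1L, ],
            total_cost = sum(trace$disc_cost), total_qaly = sum(trace$disc_qaly))
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost Incremental cost (yen), intervention minus comparator.
#' @param delta_qaly Incremental QALYs.
#' @return A list with `icer` (yen/QALY, `NA` unless both increments are
#'   finite and the ratio is defined) and `status`: `"ratio"` when
#'   `delta_qaly > 0` and `delta_cost > 0`, `"dominant"` (cheaper, no less
#'   effective), `"dominated"` (costlier, no more effective),
#'   `"indifferent"` (both zero), or `"undefined"` (no QALY gain at positive
#'   cost).
#' @export
#' @examples
#' compute_icer(3198687, 0.80)    # ratio
#' compute_icer(-522293, 0.80)    # dominant
compute_icer <- function(delta_cost, delta_qaly) {
  status <- if (delta_cost == 0 && delta_qaly == 0) "indifferent"
  else if (delta_cost <= 0 && delta_qaly >= 0) "dominant"
  else if (delta_qaly == 0 && delta_cost > 0) "undefined"
  else if (delta_cost >= 0 && delta_qaly <= 0) "dominated"
  else if (delta_qaly > 0 && delta_cost > 0) "ratio"
  else "undefined"
  icer <- if (status %in% c("ratio")) delta_cost / delta_qaly
  else if (status == "dominant" && delta_qaly > 0) delta_cost / delta_qaly
  else NA_real_
  list(icer = icer, status = status)
}

#' Run both arms and summarise cost-effectiveness
#'
#' Runs the TAI and SBC arms of the cohort model under the parameter set's
#' perspective and returns discounted lifetime totals, increments and the
#' ICER.
#'
#' @param params An `nbd_parameters` object.
#' @return An object of class `nbd_ce`: a list with `traces` (named list of
#'   `nbd_trace`), `summary` (per-arm tibble) and scalar elements
#'   `delta_cost`, `delta_qaly`, `icer`, `icer_status`, `perspective`,
#'   `fee_per_month`.
#' @export
#' @examples
#' \donttest{
#' res <- run_base_case(load_parameters())
#' glance(res)
#' }
run_base_case <- function(params) {
  traces <- list(TAI = run_cohort(params, "TAI"), SBC = run_cohort(params, "SBC"))
  cost <- vapply(traces, attr, numeric(1), "total_cost")
  qaly <- vapply(traces, attr, numeric(1), "total_qaly")
  d_cost <- cost[["TAI"]] - cost[["SBC"]]
  d_qaly <- qaly[["TAI"]] - qaly[["SBC"]]
  ic <- compute_icer(d_cost, d_qaly)
  structure(list(
    traces = traces,
    summary = tibble(arm = names(traces), cost = unname(cost), qaly = unname(qaly)),
    delta_cost = d_cost, delta_qaly = d_qaly,
    icer = ic$icer, icer_status = ic$status,
    perspective = params$settings$perspective,
    fee_per_month = params$settings$tai_procedure_fee_per_month),
    class = "nbd_ce")
}

#' Run the model under a given perspective
#'
#' @param params An `nbd_parameters` object.
#' @param perspective `"payer"`, `"societal_absenteeism"` (adds
#'   absenteeism-only productivity losses) or `"societal_full"` (absenteeism
#'   plus presenteeism).
#' @return An `nbd_ce` object (see [run_base_case()]).
#' @export
run_scenario <- function(params, perspective = c("payer", "societal_absenteeism",
                                                 "societal_full")) {
  perspective <- match.arg(perspective)
  params$settings$perspective <- perspective
  validate_parameters(params)
  run_base_case(params)
}

#' @export
print.nbd_ce <- function(x, ...) {
  cat(sprintf("<nbd_ce> perspective %s, TAI fee %s yen/month\n",
              x$perspective, format(x$fee_per_month)))
  print(x$summary)
  cat(sprintf("  delta cost %s yen, delta QALY %.4f, ICER %s (%s)\n",
              format(round(x$delta_cost)), x$delta_qaly,
              if (is.na(x$icer)) "-" else format(round(x$icer)), x$icer_status))
  invisible(x)
}

#' @export
tidy.nbd_ce <- function(x, ...) x$summary

#' @export
glance.nbd_ce <- function(x, ...) {
  tibble(perspective = x$perspective, fee_per_month = x$fee_per_month,
         cost_tai = x$summary$cost[x$summary$arm == "TAI"],
         cost_sbc = x$summary$cost[x$summary$arm == "SBC"],
         qaly_tai = x$summary$qaly[x$summary$arm == "TAI"],
         qaly_sbc = x$summary$qaly[x$summary$arm == "SBC"],
         delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
         icer = x$icer, icer_status = x$icer_status)
}

#' @export
tidy.nbd_trace <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(dplyr::all_of(health_states()),
                        names_to = "state", values_to = "occupancy") %>%
    mutate(arm = attr(x, "arm"), .before = 1L)
}
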