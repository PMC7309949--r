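#' Load the model parameter set
#'
#' Reads a structured YAML configuration holding the five parameter blocks of
#' the decision model (`settings`, `clinical`, `utility`, `cost`,
#' `productivity`), fills every omitted field from the packaged base-case
#' defaults, validates all invariants, and attaches the packaged life table.
#'
#' The packaged defaults are the calibrated Japanese base case: half-yearly
#' cycles, 2% annual discounting, cohort entering at age 51.46 (78.3% male),
#' six-monthly UTI rates 0.512 (SBC) / 0.195 (TAI), a 60/40
#' responder/non-responder split on TAI entry with 60% per-cycle withdrawal of
#' non-responders, a 0.033% per-cycle stoma construction rate, state utilities
#' 0.533 / 0.470 / 0.479 / 0.564 (TAI responder / TAI non-responder / SBC /
#' stoma), and the fee-schedule costs in yen.
#'
#' @param config Path to a YAML file with (possibly partial) overrides, or
#'   `NULL` for the packaged base case.
#' @param overrides A nested named list of overrides applied on top of
#'   `config` (same shape as the YAML), e.g.
#'   `list(settings = list(annual_discount_rate = 0))`.
#' @param lifetable Optional life table as returned by [load_lifetable()];
#'   defaults to the packaged synthetic table.
#'
#' @return An object of class `nbd_parameters`: a named list with elements
#'   `settings`, `clinical`, `utility`, `cost`, `productivity` and
#'   `lifetable`.
#' @export
#' @examples
#' p <- load_parameters()
#' p$clinical$uti_rate_sbc_per_cycle
#' p2 <- load_parameters(overrides = list(settings = list(perspective = "societal_full")))
load_parameters <- function(config = NULL, overrides = list(), lifetable = NULL) {
  defaults <- yaml::read_yaml(nbdcea_file("base_case.yaml"))
  user <- if (is.null(config)) list() else yaml::read_yaml(config)
  merged <- modifyList(defaults, user)
  merged <- modifyList(merged, overrides)
  params <- structure(merged[c("settings", "clinical", "utility", "cost", "productivity")],
                      class = "nbd_parameters")
  params$lifetable <- if (is.null(lifetable)) load_lifetable() else lifetable
  validate_parameters(params)
}

#' Construct a parameter set from the packaged defaults
#'
#' Convenience wrapper around [load_parameters()] taking overrides as
#' arguments: `nbd_parameters(settings = list(annual_discount_rate = 0))`.
#'
#' @param ... Named blocks (`settings`, `clinical`, `utility`, `cost`,
#'   `productivity`), each a named list of fields to override.
#' @inheritParams load_parameters
#' @return An `nbd_parameters` object.
#' @export
nbd_parameters <- function(..., lifetable = NULL) {
  load_parameters(overrides = list(...), lifetable = lifetable)
}

nbdcea_file <- function(...) {
  system.file("extdata", ..., package = "nbdcea", mustWork = TRUE)
}

abort_invalid <- function(field, msg) {
  abort(sprintf("invalid parameter `%s`: %s", field, msg), class = "nbdcea_validation_error")
}

check_range <- function(x, field, lo = -Inf, hi = Inf, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_invalid(field, "must be a single non-missing number")
  ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) abort_invalid(field, sprintf("value %g outside [%g, %g]", x, lo, hi))
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every invariant of the model parameter blocks: discount rate in
#' \[0, 1), positive cycle length and procedure fee, rates and costs
#' non-negative, fractions and probabilities in \[0, 1\], state utilities in
#' \[-1, 1\], non-negative event disutilities, and the UTI treatment split
#' summing to one (within 1e-9).  Validation errors name the offending field.
#'
#' @param params An `nbd_parameters` object.
#' @return `params`, invisibly unchanged, if valid; otherwise an error of
#'   class `nbdcea_validation_error`.
#' @export
validate_parameters <- function(params) {
  s <- params$settings
  check_range(s$cycle_length_years, "settings.cycle_length_years", 0, Inf, lo_open = TRUE)
  check_range(s$annual_discount_rate, "settings.annual_discount_rate", 0, 1, hi_open = TRUE)
  check_range(s$start_age, "settings.start_age", 0, s$max_age)
  check_range(s$max_age, "settings.max_age", s$start_age, 130)
  check_range(s$male_fraction, "settings.male_fraction", 0, 1)
  check_range(s$tai_procedure_fee_per_month, "settings.tai_procedure_fee_per_month",
              0, Inf, lo_open = TRUE)
  check_range(s$excess_mortality_smr, "settings.excess_mortality_smr", 0, Inf, lo_open = TRUE)
  if (!s$perspective %in% c("payer", "societal_absenteeism", "societal_full"))
    abort_invalid("settings.perspective", "must be payer, societal_absenteeism or societal_full")
  if (!s$withdrawal_mode %in% c("per_cycle", "immediate"))
    abort_invalid("settings.withdrawal_mode", "must be per_cycle or immediate")
  if (!s$stoma_events_mode %in% c("sbc_rates", "management_only"))
    abort_invalid("settings.stoma_events_mode", "must be sbc_rates or management_only")
  if (!is.logical(s$half_cycle_correction))
    abort_invalid("settings.half_cycle_correction", "must be logical")

  cl <- params$clinical
  for (f in c("responder_fraction", "nonresponder_withdrawal_per_cycle",
              "uti_rate_sbc_per_cycle", "uti_rate_tai_per_cycle",
              "nursing_rate_sbc", "nursing_rate_tai",
              "stoma_rate_per_cycle", "laparoscopic_fraction"))
    check_range(cl[[f]], paste0("clinical.", f), 0, 1)
  for (f in c("hosp_decubitus_sbc", "hosp_decubitus_tai",
              "hosp_other_sbc", "hosp_other_tai", "nursing_visits_per_week"))
    check_range(cl[[f]], paste0("clinical.", f), 0, Inf)
  check_range(cl$hospitalization_recall_years, "clinical.hospitalization_recall_years",
              0, Inf, lo_open = TRUE)
  check_range(cl$nbds_baseline, "clinical.nbds_baseline", 0, 47)
  split <- cl$uti_treatment_split
  for (f in names(split))
    check_range(split[[f]], paste0("clinical.uti_treatment_split.", f), 0, 1)
  if (abs(sum(unlist(split)) - 1) > 1e-9)
    abort_invalid("clinical.uti_treatment_split",
                  sprintf("components sum to %.10f, not 1", sum(unlist(split))))

  u <- params$utility
  for (f in c("u_responder", "u_nonresponder", "u_sbc", "u_stoma"))
    check_range(u[[f]], paste0("utility.", f), -1, 1)
  for (f in c("du_uti_per_event", "du_hosp_per_event"))
    check_range(u[[f]], paste0("utility.", f), 0, Inf)

  for (f in names(params$cost))
    check_range(params$cost[[f]], paste0("cost.", f), 0, Inf)

  pr <- params$productivity
  check_range(pr$employment_rate, "productivity.employment_rate", 0, 1)
  for (blk in c("absenteeism", "presenteeism"))
    for (f in names(pr[[blk]]))
      check_range(pr[[blk]][[f]], paste0("productivity.", blk, ".", f), 0, 1)
  for (f in names(pr$wage_per_month))
    check_range(pr$wage_per_month[[f]], paste0("productivity.wage_per_month.", f), 0, Inf)

  invisible(params)
}

#' @export
print.nbd_parameters <- function(x, ...) {
  cat("<nbd_parameters>\n")
  cat(sprintf("  perspective: %s, fee %s yen/month, discount %.1f%%/yr\n",
              x$settings$perspective, format(x$settings$tai_procedure_fee_per_month),
              100 * x$settings$annual_discount_rate))
  cat(sprintf("  cohort: start age %.2f, %.1f%% male, horizon to age %d (%.1f-year cycles)\n",
              x$settings$start_age, 100 * x$settings$male_fraction,
              as.integer(x$settings$max_age), x$settings$cycle_length_years))
  cat(sprintf("  %d sweepable scalar parameters\n", nrow(parameter_registry(x))))
  invisible(x)
}

# ---- flat path access -------------------------------------------------------

#' Get or set a parameter by its flat path
#'
#' Paths are dot-separated, e.g. `"clinical.uti_rate_sbc_per_cycle"` or
#' `"clinical.uti_treatment_split.outpatient"`, as listed by
#' [parameter_registry()].  `param_set()` returns a modified copy and does
#' not revalidate; sensitivity analyses use it for controlled perturbations.
#'
#' @param params An `nbd_parameters` object.
#' @param path Dot-separated field path.
#' @param value Replacement value (for `param_set()`).
#' @return `param_get()`: the value; `param_set()`: the modified parameter
#'   set.
#' @export
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  purrr::reduce(parts, function(acc, p) acc[[p]], .init = params)
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- paste0("params", paste0("[['", parts, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  params
}

#' Registry of sweepable scalar parameters
#'
#' Enumerates the scalar model inputs that deterministic and probabilistic
#' sensitivity analyses act on, together with the distribution family each is
#' given in the PSA: `beta` for utilities and probabilities bounded in
#' \[0, 1\], `gamma` for costs and for unbounded event frequencies.
#' Structural settings (cycle length, horizon, perspective) and the simplex
#' UTI treatment split are excluded.
#'
#' @param params An `nbd_parameters` object.
#' @return A tibble with columns `path`, `value` and `family`.
#' @export
parameter_registry <- function(params) {
  beta_paths <- c(
    "clinical.responder_fraction", "clinical.nonresponder_withdrawal_per_cycle",
    "clinical.uti_rate_sbc_per_cycle", "clinical.uti_rate_tai_per_cycle",
    "clinical.nursing_rate_sbc", "clinical.nursing_rate_tai",
    "clinical.stoma_rate_per_cycle", "clinical.laparoscopic_fraction",
    "utility.u_responder", "utility.u_nonresponder", "utility.u_sbc",
    "utility.u_stoma", "utility.du_uti_per_event", "utility.du_hosp_per_event")
  gamma_paths <- c(
    "clinical.hosp_decubitus_sbc", "clinical.hosp_decubitus_tai",
    "clinical.hosp_other_sbc", "clinical.hosp_other_tai",
    paste0("cost.", setdiff(names(params$cost),
                            c("peristeen_system_set_price", "peristeen_sets_per_year",
                              "accessory_annual_cost"))))
  if (params$settings$perspective != "payer")
    beta_paths <- c(beta_paths, "productivity.employment_rate")
  reg <- tibble(
    path = c(beta_paths, gamma_paths),
    family = rep(c("beta", "gamma"), c(length(beta_paths), length(gamma_paths))))
  reg$value <- purrr::map_dbl(reg$path, ~ param_get(params, .x))
  reg[c("path", "value", "family")]
}

#' @export
tidy.nbd_parameters <- function(x, ...) {
  flat <- function(block, prefix) {
    leaves <- rapply(block, identity, how = "unlist")
    tibble(parameter = paste0(prefix, ".", names(leaves)),
           value = as.character(unname(leaves)))
  }
  bind_rows(purrr::imap(x[c("settings", "clinical", "utility", "cost", "productivity")], flat))
}

# ---- derived cost quantities ------------------------------------------------

#' Derived base-case cost quantities
#'
#' Arithmetic combinations of fee-schedule entries that the model consumes:
#' the annual Peristeen irrigation-system cost (sets per year times the set
#' price), the total annual device cost (system plus accessory units), the
#' laparoscopic/open weighted stoma surgery fee and hospitalization cost, the
#' treatment-split weighted expected cost of one UTI episode, and the weekly
#' visiting-nursing cost (visits times the per-day fee plus the once-weekly
#' long-hours premium).
#'
#' @param params An `nbd_parameters` object.
#' @return A named list of scalars (yen):
#'   `system_cost_per_year`, `device_cost_per_year`, `stoma_surgery_fee`,
#'   `stoma_surgery_hospitalization`, `uti_episode_cost`,
#'   `weekly_nursing_cost`.
#' @export
#' @examples
#' derived_costs(load_parameters())$stoma_surgery_fee  # 113955
derived_costs <- function(params) {
  co <- params$cost
  cl <- params$clinical
  lap <- cl$laparoscopic_fraction
  split <- cl$uti_treatment_split
  list(
    system_cost_per_year = co$peristeen_sets_per_year * co$peristeen_system_set_price,
    device_cost_per_year = co$peristeen_sets_per_year * co$peristeen_system_set_price +
      co$accessory_annual_cost,
    stoma_surgery_fee = lap * co$stoma_fee_laparoscopic + (1 - lap) * co$stoma_fee_open,
    stoma_surgery_hospitalization = lap * co$stoma_hosp_laparoscopic +
      (1 - lap) * co$stoma_hosp_open,
    uti_episode_cost = split$hospitalized * co$uti_cost_hospitalized +
      split$outpatient * co$uti_cost_outpatient +
      split$untreated * co$uti_cost_untreated,
    weekly_nursing_cost = cl$nursing_visits_per_week * co$nursing_cost_per_visit +
      co$nursing_premium_per_week)
}
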