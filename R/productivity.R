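#' NBDS severity category
#'
#' Bins a Neurogenic Bowel Dysfunction score into the standard severity
#' categories: very minor (< 7), minor (7-9), moderate (10-13) and severe
#' (14 and over).  Non-integer scores are rounded half-up before binning.
#'
#' @param score NBDS value(s) in \[0, 47\].
#' @return A character vector with values `"below_minor"`, `"minor"`,
#'   `"moderate"`, `"severe"`.
#' @export
#' @examples
#' nbds_category(c(16.74, 10.74, 9, 10))
nbds_category <- function(score) {
  if (any(score < 0 | score > 47)) abort("NBDS must lie in [0, 47]")
  r <- floor(score + 0.5)  # half-up rounding
  dplyr::case_when(r < 7 ~ "below_minor",
                   r <= 9 ~ "minor",
                   r <= 13 ~ "moderate",
                   TRUE ~ "severe")
}

wage_for_age <- function(age, wages) {
  dplyr::case_when(age < 55 ~ wages$age_50_54,  # under-50s use the 50-54 band
                   age < 60 ~ wages$age_55_59,
                   age < 65 ~ wages$age_60_64,
                   age < 70 ~ wages$age_65_69,
                   TRUE ~ wages$age_70_plus)
}

#' Human-capital productivity loss per person-cycle
#'
#' Expected productivity cost for one cohort member over one cycle:
#' employment rate times the age-band monthly wage times the months per
#' cycle times the loss fraction.  The loss fraction is the category's
#' absenteeism rate in `"absenteeism"` mode, and the sum of absenteeism and
#' presenteeism (capped at 1) in `"absenteeism_plus_presenteeism"` mode.
#' Scores below the minor band, and the minor band itself, carry zero
#' absenteeism.
#'
#' @param age Age in years.
#' @param category Severity category from [nbds_category()].
#' @param prod_params The `productivity` block of an `nbd_parameters`
#'   object.
#' @param mode `"absenteeism"` or `"absenteeism_plus_presenteeism"`.
#' @param cycle_years Cycle length in years.
#' @return Cost in yen per person-cycle.
#' @export
#' @examples
#' p <- load_parameters()
#' productivity_loss_per_cycle(52, "severe", p$productivity)  # ~74 750 yen
productivity_loss_per_cycle <- function(age, category, prod_params,
                                        mode = c("absenteeism",
                                                 "absenteeism_plus_presenteeism"),
                                        cycle_years = 0.5) {
  mode <- match.arg(mode)
  absent <- switch(category, below_minor = 0, minor = prod_params$absenteeism$minor,
                   moderate = prod_params$absenteeism$moderate,
                   severe = prod_params$absenteeism$severe)
  loss <- if (mode == "absenteeism") absent else {
    present <- switch(category, below_minor = 0, minor = prod_params$presenteeism$minor,
                      moderate = prod_params$presenteeism$moderate,
                      severe = prod_params$presenteeism$severe)
    min(1, absent + present)
  }
  prod_params$employment_rate * wage_for_age(age, prod_params$wage_per_month) *
    (cycle_years * 12) * loss
}

# NBDS attributed to each alive health state for productivity costing:
# standard-care states sit at the survey baseline, TAI responders at
# baseline + responder improvement, TAI non-responders at baseline +
# deterioration; post-stoma scores are not observed, so the stoma state
# keeps the baseline (severe) score.
state_nbds_scores <- function(params) {
  cl <- params$clinical
  clamp <- function(x) pmin(pmax(x, 0), 47)
  list(TAI_RESPONDER = clamp(cl$nbds_baseline + cl$nbds_delta_responder),
       TAI_NONRESPONDER = clamp(cl$nbds_baseline + cl$nbds_delta_nonresponder),
       RESUME_SBC = cl$nbds_baseline,
       SBC = cl$nbds_baseline,
       STOMA = cl$nbds_baseline)
}
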