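#' Load a background-mortality life table
#'
#' The cohort model needs an annual death probability by age and sex to drive
#' its absorbing Dead state over the lifetime horizon.  The packaged table is
#' a *synthetic* abridged life table: Gompertz-Makeham hazards calibrated to
#' approximate contemporary Japanese mortality (life expectancy at birth
#' about 82 years for men and 87 for women), tabulated at single years of age
#' 0-110 with the final probability set to 1.  It is a stand-in, not official
#' vital statistics; any table with the same columns can be dropped in.
#'
#' @param path Path to a CSV with columns `age`, `qx_male`, `qx_female`
#'   (annual death probabilities), or `NULL` for the packaged synthetic
#'   table.
#' @return A tibble with columns `age`, `qx_male`, `qx_female`.
#' @export
load_lifetable <- function(path = NULL) {
  if (is.null(path)) path <- nbdcea_file("lifetable_synthetic.csv")
  lt <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("age", "qx_male", "qx_female") %in% names(lt)))
  if (any(lt$qx_male < 0 | lt$qx_male > 1 | lt$qx_female < 0 | lt$qx_female > 1))
    abort("life table probabilities must lie in [0, 1]")
  as_tibble(lt[order(lt$age), ])
}

#' Per-cycle death probability at a given age
#'
#' Looks up the annual death probability at `floor(age)` (clamped to the
#' table's support), mixes the sexes by the cohort male fraction on the
#' probability scale, applies the excess-mortality multiplier on the hazard
#' scale (`1 - (1 - q)^smr`), and converts to the cycle length
#' (`1 - (1 - q)^cycle_years`).
#'
#' @param lifetable A tibble from [load_lifetable()].
#' @param age Age in years (vectorised).
#' @param male_fraction Fraction of the cohort that is male.
#' @param smr Standardised mortality ratio multiplier (1 = general
#'   population).
#' @param cycle_years Cycle length in years.
#' @return Death probability per cycle, same length as `age`.
#' @export
cycle_death_prob <- function(lifetable, age, male_fraction, smr = 1, cycle_years = 0.5) {
  idx <- pmin(pmax(floor(age), min(lifetable$age)), max(lifetable$age)) -
    min(lifetable$age) + 1L
  q_annual <- male_fraction * lifetable$qx_male[idx] +
    (1 - male_fraction) * lifetable$qx_female[idx]
  q_annual <- 1 - (1 - q_annual)^smr
  1 - (1 - q_annual)^cycle_years
}
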