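# signed cost-per-QALY ratio used for tornado ranges (NA when no QALY difference)
icer_value <- function(ce) if (ce$delta_qaly == 0) NA_real_ else ce$delta_cost / ce$delta_qaly

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full model twice per parameter - once at `(1 - span)` and once
#' at `(1 + span)` times its base value, everything else held at base - and
#' records the resulting cost-per-QALY ratio and incremental net monetary
#' benefit at a reference willingness to pay.  Probability-type parameters
#' pushed outside \[0, 1\] are clamped, and the clamping is recorded in the
#' output.
#'
#' Rows are sorted by the width of the *net-monetary-benefit* interval, not
#' the ICER interval: a utility sweep can push the incremental QALY through
#' zero, where the ICER has a pole, making the raw ICER range measure
#' distance to the pole rather than influence on the decision.  NMB is
#' linear in both increments and ranks influence stably; the ICER endpoints
#' are still reported.
#'
#' @param params An `nbd_parameters` object (the base case).
#' @param paths Character vector of parameter paths to sweep (default: the
#'   full [parameter_registry()]).
#' @param span Relative variation (default 0.2 for +/-20%).
#' @param wtp_ref Reference willingness to pay for the NMB ranking
#'   (default 5 million yen/QALY, the published Japanese threshold).
#' @return A tibble of class `nbd_tornado` with columns `path`, `base_value`,
#'   `icer_low`, `icer_high`, `range` (ICER interval width), `nmb_low`,
#'   `nmb_high`, `nmb_range` (the sort key), `clamped`; the base-case ICER
#'   is attached as attribute `base_icer`.
#' @export
one_way_sweep <- function(params, paths = NULL, span = 0.2, wtp_ref = 5e6) {
  reg <- parameter_registry(params)
  if (is.null(paths)) paths <- reg$path
  if (!all(paths %in% reg$path))
    abort(paste("unknown parameter path(s):",
                paste(setdiff(paths, reg$path), collapse = ", ")))
  base_ce <- run_base_case(params)
  rows <- purrr::map(paths, function(pth) {
    fam <- reg$family[reg$path == pth]
    v <- param_get(params, pth)
    vals <- v * c(1 - span, 1 + span)
    clamped <- FALSE
    if (fam == "beta" && any(vals > 1)) { vals <- pmin(vals, 1); clamped <- TRUE }
    ces <- lapply(vals, function(x) run_base_case(param_set(params, pth, x)))
    icers <- vapply(ces, icer_value, numeric(1))
    nmbs <- vapply(ces, function(ce) wtp_ref * ce$delta_qaly - ce$delta_cost,
                   numeric(1))
    tibble(path = pth, base_value = v, icer_low = icers[1], icer_high = icers[2],
           range = abs(icers[2] - icers[1]),
           nmb_low = nmbs[1], nmb_high = nmbs[2],
           nmb_range = abs(nmbs[2] - nmbs[1]), clamped = clamped)
  })
  out <- bind_rows(rows) %>% arrange(desc(.data$nmb_range))
  structure(out, class = c("nbd_tornado", class(out)),
            base_icer = icer_value(base_ce), span = span, wtp_ref = wtp_ref)
}

#' Probabilistic sensitivity analysis specification
#'
#' Assigns each registry parameter its sampling distribution: gamma for
#' costs and unbounded event frequencies, beta for utilities and
#' probabilities, both parameterised by method of moments around the
#' base-case mean with standard deviation `cv * mean`.  Where the implied
#' beta variance is infeasible (`sd^2 >= mean * (1 - mean)`) the standard
#' deviation is shrunk to 99% of the feasible bound, recorded in the spec.
#'
#' @param params An `nbd_parameters` object.
#' @param cv Coefficient of variation (default 0.2); either a scalar or a
#'   named vector keyed by parameter path.
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed.
#' @return A list of class `nbd_psa_spec` with the per-parameter table and
#'   settings.
#' @export
psa_spec <- function(params, cv = 0.2, n_draws = 10000, seed = 1) {
  reg <- parameter_registry(params)
  reg$cv <- if (length(cv) == 1L) rep(cv, nrow(reg)) else unname(cv[reg$path])
  if (any(is.na(reg$cv) | reg$cv < 0)) abort("cv must be non-negative for every path")
  reg$sd <- reg$cv * reg$value
  infeasible <- reg$family == "beta" & reg$value > 0 & reg$value < 1 &
    reg$sd^2 >= reg$value * (1 - reg$value)
  if (any(infeasible)) {
    reg$sd[infeasible] <- 0.99 * sqrt(reg$value[infeasible] * (1 - reg$value[infeasible]))
    warn(sprintf("beta moments infeasible for %d parameter(s); sd shrunk to 99%% of bound",
                 sum(infeasible)))
  }
  reg$shrunk <- infeasible
  structure(list(table = reg, params = params, n_draws = n_draws, seed = seed),
            class = "nbd_psa_spec")
}

#' Draw one parameter set from a PSA specification
#'
#' Reproducible by `(seed, k)`: the RNG stream for draw `k` is keyed on the
#' spec seed and the draw index.  Gamma draws use shape `1/cv^2`, scale
#' `mean * cv^2`; beta draws use method-of-moments shapes from
#' `(mean, sd)`.  Zero-variance (cv = 0) or boundary-mean parameters
#' collapse to their base-case values.
#'
#' @param spec An `nbd_psa_spec`.
#' @param k Draw index (1-based).
#' @return An `nbd_parameters` object with sampled values.
#' @export
draw_parameters <- function(spec, k) {
  tab <- spec$table
  draws <- with_local_seed(mix_seed(spec$seed, k), {
    vapply(seq_len(nrow(tab)), function(i) {
      m <- tab$value[i]; s <- tab$sd[i]
      if (s == 0 || m == 0 || (tab$family[i] == "beta" && m >= 1)) return(m)
      if (tab$family[i] == "gamma") {
        cv2 <- (s / m)^2
        rgamma(1, shape = 1 / cv2, scale = m * cv2)
      } else {
        nu <- m * (1 - m) / s^2 - 1
        rbeta(1, m * nu, (1 - m) * nu)
      }
    }, numeric(1))
  })
  p <- spec$params
  for (i in seq_len(nrow(tab))) p <- param_set(p, tab$path[i], draws[i])
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples `n_draws` joint parameter sets from the PSA distributions, runs
#' the full two-arm model for each, and collects per-draw arm totals and
#' increments (the cost-effectiveness plane point cloud).
#'
#' @inheritParams psa_spec
#' @param spec Optionally a prebuilt `nbd_psa_spec` (overrides `cv`,
#'   `n_draws`, `seed`).
#' @return An object of class `nbd_psa`: a tibble with columns `draw`,
#'   `cost_tai`, `cost_sbc`, `qaly_tai`, `qaly_sbc`, `d_cost`, `d_qaly`.
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1, cv = 0.2, spec = NULL) {
  if (is.null(spec)) spec <- psa_spec(params, cv = cv, n_draws = n_draws, seed = seed)
  rows <- purrr::map(seq_len(spec$n_draws), function(k) {
    ce <- run_base_case(draw_parameters(spec, k))
    g <- glance(ce)
    tibble(draw = k, cost_tai = g$cost_tai, cost_sbc = g$cost_sbc,
           qaly_tai = g$qaly_tai, qaly_sbc = g$qaly_sbc,
           d_cost = g$delta_cost, d_qaly = g$delta_qaly)
  })
  out <- bind_rows(rows)
  structure(out, class = c("nbd_psa", class(out)), seed = spec$seed)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `w`, the probability that the
#' intervention is cost-effective: the fraction of PSA draws with
#' non-negative net monetary benefit `w * dQALY - dCost`.
#'
#' @param draws An `nbd_psa` (or any data frame with `d_cost`, `d_qaly`).
#' @param wtp_grid Willingness-to-pay grid in yen/QALY (default 0 to 10
#'   million in 100 000-yen steps).
#' @return A tibble of class `nbd_ceac` with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 1e7, by = 1e5)) {
  if (length(wtp_grid) < 1) abort("WTP grid must be non-empty")
  if (nrow(draws) < 1) abort("at least one PSA draw is required")
  p <- vapply(wtp_grid, function(w)
    mean(w * draws$d_qaly - draws$d_cost >= 0), numeric(1))
  out <- tibble(wtp = wtp_grid, prob_cost_effective = p)
  structure(out, class = c("nbd_ceac", class(out)))
}

#' @export
glance.nbd_psa <- function(x, ...) {
  tibble(n_draws = nrow(x),
         mean_d_cost = mean(x$d_cost), mean_d_qaly = mean(x$d_qaly),
         prob_dominant = mean(x$d_cost <= 0 & x$d_qaly >= 0))
}
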