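#' Relative risk
#'
#' @param p_treated Event rate under treatment.
#' @param p_control Event rate under control (> 0).
#' @return `p_treated / p_control`.
#' @export
#' @examples
#' relative_risk(0.195, 0.512)  # 0.381
relative_risk <- function(p_treated, p_control) {
  if (any(p_treated < 0) || any(p_control < 0)) abort("rates must be non-negative")
  if (any(p_control == 0)) abort("relative risk undefined: control rate is zero")
  p_treated / p_control
}

#' Per-cycle event probability from time-to-event data
#'
#' Fits a constant (exponential) hazard by maximum likelihood - events
#' divided by total person-time - and converts it to a per-cycle probability
#' `1 - exp(-lambda * cycle_years)`.  Subjects without the event contribute
#' censored follow-up time.
#'
#' @param data A data frame with columns `duration_years` (> 0) and `event`
#'   (0/1 or logical).
#' @param cycle_years Cycle length in years (default 0.5).
#' @return A list with `lambda` (per year), `prob_per_cycle`, `events`,
#'   `person_years`.
#' @export
#' @examples
#' exponential_rate_per_cycle(
#'   data.frame(duration_years = rep(10, 10), event = c(1, rep(0, 9))))
exponential_rate_per_cycle <- function(data, cycle_years = 0.5) {
  if (any(data$duration_years <= 0)) abort("durations must be positive")
  py <- sum(data$duration_years)
  if (py <= 0) abort("total person-time must be positive")
  ev <- sum(as.integer(data$event))
  lambda <- ev / py
  list(lambda = lambda, prob_per_cycle = 1 - exp(-lambda * cycle_years),
       events = ev, person_years = py)
}

#' Fit the nursing-visit logistic model
#'
#' Maximum-likelihood logistic regression of the visiting-nursing indicator
#' on NBDS, with age, a male indicator and hand-function impairment as
#' covariates, mirroring the regression through which improved bowel
#' function reduces nursing utilisation in the model's alternative
#' regression-based mode.
#'
#' @param survey A survey tibble with columns `nursing_visit`, `nbds`,
#'   `age`, `gender`, `hand_impaired`.
#' @param min_n Minimum number of records (default 50).
#' @return An object of class `nbd_nursing_model` wrapping the `glm` fit.
#' @export
fit_nursing_model <- function(survey, min_n = 50) {
  if (nrow(survey) < min_n)
    abort(sprintf("nursing fit needs at least %d records, got %d", min_n, nrow(survey)))
  y <- as.integer(survey$nursing_visit)
  if (length(unique(y)) < 2L)
    abort("nursing fit failed: outcome is constant (complete separation)")
  dat <- data.frame(y = y, nbds = survey$nbds, age = survey$age,
                    male = as.integer(survey$gender == "male"),
                    hand = as.integer(survey$hand_impaired))
  fit <- suppressWarnings(glm(y ~ nbds + age + male + hand, data = dat,
                              family = binomial()))
  if (!fit$converged) abort("nursing logistic fit did not converge")
  if (any(abs(coef(fit)) > 15))
    abort("nursing fit unstable (likely separation): extreme coefficients")
  structure(list(fit = fit), class = "nbd_nursing_model")
}

#' Predicted nursing-visit probability
#'
#' @param model An `nbd_nursing_model`.
#' @param nbds,age NBDS and age values.
#' @param male Male indicator (0/1) or fraction.
#' @param hand Hand-impairment indicator (0/1) or fraction.
#' @return Probability in (0, 1).
#' @export
predict_nursing_rate <- function(model, nbds, age, male, hand) {
  nd <- data.frame(nbds = nbds, age = age, male = male, hand = hand)
  as.numeric(stats::predict(model$fit, newdata = nd, type = "response"))
}

#' @export
tidy.nbd_nursing_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.nbd_nursing_model <- function(x, ...) {
  tibble(n = length(x$fit$y), deviance = x$fit$deviance,
         null_deviance = x$fit$null.deviance, aic = x$fit$aic,
         converged = x$fit$converged)
}
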