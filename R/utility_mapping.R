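#' Load an EQ-5D-5L value set (tariff)
#'
#' A value set maps an EQ-5D-5L profile (five dimensions - mobility,
#' self-care, usual activities, pain/discomfort, anxiety/depression - each at
#' level 1-5) to a utility anchored at 1 for full health (1,1,1,1,1).  The
#' packaged file is a *synthetic* stylized additive tariff (per-dimension,
#' per-level decrements subtracted from 1), shipped because the package does
#' not bundle any country's licensed tariff; a real national value set in the
#' same three-column format can be dropped in without code changes.
#'
#' @param path CSV with columns `dimension` (`mo`, `sc`, `ua`, `pd`, `ad`),
#'   `level` (1-5) and `decrement`; `NULL` for the packaged synthetic
#'   tariff.
#' @return A tibble of class `nbd_value_set`.
#' @export
load_value_set <- function(path = NULL) {
  if (is.null(path)) path <- nbdcea_file("value_set_synthetic.csv")
  vs <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("dimension", "level", "decrement") %in% names(vs)))
  if (!setequal(unique(vs$dimension), eq5d_dimensions()) ||
      !all(sort(unique(vs$level)) == 1:5))
    abort("value set must cover dimensions mo,sc,ua,pd,ad at levels 1-5")
  if (any(vs$decrement[vs$level == 1] != 0))
    abort("value set must anchor full health (all level-1 decrements zero)")
  structure(as_tibble(vs), class = c("nbd_value_set", class(as_tibble(vs))))
}

eq5d_dimensions <- function() c("mo", "sc", "ua", "pd", "ad")

# decrement lookup matrix: 5 dimensions x 5 levels
value_set_matrix <- function(value_set) {
  m <- matrix(0, 5, 5, dimnames = list(eq5d_dimensions(), 1:5))
  for (i in seq_len(nrow(value_set)))
    m[value_set$dimension[i], value_set$level[i]] <- value_set$decrement[i]
  m
}

#' Utility of EQ-5D-5L profiles under a value set
#'
#' @param value_set An `nbd_value_set` from [load_value_set()].
#' @param profiles An integer vector of 5 levels, or an n x 5 matrix of
#'   levels, in dimension order mo, sc, ua, pd, ad.
#' @return Utility value(s), 1 for full health.
#' @export
profile_utility <- function(value_set, profiles) {
  m <- value_set_matrix(value_set)
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (ncol(profiles) != 5 || any(profiles < 1 | profiles > 5))
    abort("profiles must have five levels in 1..5")
  dec <- vapply(1:5, function(d) m[d, profiles[, d]], numeric(nrow(profiles)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  1 - rowSums(dec)
}

#' Fit the NBDS to EQ-5D-5L mapping model
#'
#' Fits, for each EQ-5D-5L dimension, a multinomial logistic regression of
#' the reported level (1-5) on NBDS with age and a male indicator as
#' covariates, by maximum likelihood ([nnet::multinom()]).  A dimension with
#' a single observed level is retained as a degenerate model predicting that
#' level with probability one.
#'
#' @param survey A survey tibble (see [generate_survey()]) with columns
#'   `nbds`, `age`, `gender` and `eq5d_mo` ... `eq5d_ad`.
#' @param min_n Minimum number of records required (default 50).
#' @return An object of class `eq5d_mapping`: per-dimension fits, observed
#'   levels and convergence flags.
#' @export
fit_eq5d_mapping <- function(survey, min_n = 50) {
  if (nrow(survey) < min_n)
    abort(sprintf("mapping fit needs at least %d records, got %d", min_n, nrow(survey)))
  dat <- data.frame(nbds = survey$nbds, age = survey$age,
                    male = as.integer(survey$gender == "male"))
  fits <- lapply(eq5d_dimensions(), function(d) {
    y <- survey[[paste0("eq5d_", d)]]
    if (any(!y %in% 1:5)) abort(sprintf("dimension %s has levels outside 1..5", d))
    lev <- sort(unique(y))
    if (length(lev) == 1L)
      return(list(type = "degenerate", level = lev, levels = lev, converged = TRUE))
    fit <- nnet::multinom(factor(y, levels = lev) ~ nbds + age + male,
                          data = dat, trace = FALSE, maxit = 500)
    if (fit$convergence != 0)
      abort(sprintf("multinomial fit failed to converge for dimension %s", d))
    list(type = "multinom", fit = fit, levels = lev, converged = TRUE)
  })
  names(fits) <- eq5d_dimensions()
  structure(list(dimensions = fits, reference = "lowest observed level"),
            class = "eq5d_mapping")
}

#' Predicted EQ-5D-5L level probabilities
#'
#' @param model An `eq5d_mapping` from [fit_eq5d_mapping()].
#' @param nbds NBDS value.
#' @param age Age in years.
#' @param male Male indicator (0/1) or male fraction for a mixed cohort.
#' @return A 5 x 5 matrix: rows mo, sc, ua, pd, ad; columns levels 1-5;
#'   each row sums to 1.
#' @export
predict_level_probs <- function(model, nbds, age, male) {
  nd <- data.frame(nbds = nbds, age = age, male = male)
  out <- matrix(0, 5, 5, dimnames = list(eq5d_dimensions(), 1:5))
  for (d in eq5d_dimensions()) {
    f <- model$dimensions[[d]]
    if (f$type == "degenerate") {
      out[d, f$level] <- 1
    } else if (f$type == "fixed") {
      out[d, ] <- f$probs
    } else {
      p <- stats::predict(f$fit, newdata = nd, type = "probs")
      if (is.null(dim(p))) p <- setNames(p, f$levels) else p <- p[1, ]
      out[d, as.integer(names(p))] <- as.numeric(p)
    }
  }
  dev <- abs(rowSums(out) - 1)
  if (any(dev > 1e-9)) abort("predicted level probabilities do not sum to 1")
  out
}

#' Assign an EQ-5D-5L level from a uniform draw
#'
#' Inverts the cumulative level probabilities with the standard
#' left-closed rule: the assigned level is the smallest `k` such that
#' `u <= P(level <= k)`; equivalently level 1 if `u <= c1`, level 2 if
#' `c1 < u <= c2`, ..., level 5 if `u > c4`.
#'
#' @param u Uniform draw(s) in \[0, 1).
#' @param cum_probs Non-decreasing cumulative probabilities of levels 1-5;
#'   the final element must equal 1 within 1e-9.
#' @return Integer level(s) 1-5.
#' @export
#' @examples
#' assign_level(0.95, cumsum(rep(0.2, 5)))  # 5
assign_level <- function(u, cum_probs) {
  if (length(cum_probs) != 5 || any(diff(cum_probs) < -1e-12) ||
      abs(cum_probs[5] - 1) > 1e-9)
    abort("cum_probs must be 5 non-decreasing values ending at 1")
  1L + (u > cum_probs[1]) + (u > cum_probs[2]) + (u > cum_probs[3]) + (u > cum_probs[4])
}

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

mix_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(key) * 104729 + 12345) %%
               .Machine$integer.max)
}

#' Monte Carlo expected utility at one NBDS value
#'
#' Repeats virtual EQ-5D-5L profile draws: per trial, one independent uniform
#' per dimension is inverted through [assign_level()] against the model's
#' cumulative level probabilities at the given NBDS and covariates, and the
#' resulting profile is valued with the tariff.  Returns the mean utility
#' over trials and its Monte Carlo standard error.  Reproducible: the RNG
#' stream is keyed by `(seed, nbds)`.
#'
#' @param model An `eq5d_mapping`.
#' @param nbds Integer NBDS in 0-47.
#' @param value_set An `nbd_value_set`.
#' @param trials Number of Monte Carlo trials (default 10000).
#' @param seed Integer seed.
#' @param age,male Covariate values (defaults: cohort means 51.46 and
#'   0.783).
#' @return A list with `utility`, `mc_se`, `trials`.
#' @export
simulate_expected_utility <- function(model, nbds, value_set, trials = 10000,
                                      seed = 1, age = 51.46, male = 0.783) {
  stopifnot(trials >= 1)
  probs <- predict_level_probs(model, nbds, age, male)
  cum <- t(apply(probs, 1, cumsum))
  m <- value_set_matrix(value_set)
  u <- with_local_seed(mix_seed(seed, nbds), {
    draws <- matrix(runif(trials * 5), trials, 5)
    dec <- vapply(1:5, function(d) {
      lev <- assign_level(draws[, d], cum[d, ])
      m[d, lev]
    }, numeric(trials))
    if (is.null(dim(dec))) dec <- matrix(dec, nrow = trials)
    1 - rowSums(dec)
  })
  list(utility = mean(u), mc_se = if (trials > 1) sd(u) / sqrt(trials) else NA_real_,
       trials = trials)
}

#' Exact expected utility by profile enumeration
#'
#' Closed-form counterpart of [simulate_expected_utility()]: sums
#' `P(profile) * tariff(profile)` over all 3125 EQ-5D-5L profiles, with
#' dimensions independent given NBDS.  Used as the oracle the Monte Carlo
#' estimate converges to.
#'
#' @inheritParams simulate_expected_utility
#' @return Expected utility (scalar).
#' @export
expected_utility_exact <- function(model, nbds, value_set, age = 51.46, male = 0.783) {
  probs <- predict_level_probs(model, nbds, age, male)
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))[, 5:1]  # mo fastest -> reorder
  colnames(grid) <- eq5d_dimensions()
  p <- vapply(seq_len(nrow(grid)), function(i)
    prod(probs[cbind(1:5, grid[i, ])]), numeric(1))
  sum(p * profile_utility(value_set, grid))
}

#' Expected-utility curve over the NBDS range
#'
#' Runs [simulate_expected_utility()] at every integer NBDS 0-47 at fixed
#' covariates.
#'
#' @inheritParams simulate_expected_utility
#' @param nbds_range Integer NBDS values to evaluate (default 0:47).
#' @return A tibble of class `nbd_utility_curve` with columns `nbds`,
#'   `utility`, `mc_se`, `trials`.
#' @export
simulate_utility_curve <- function(model, value_set, trials = 10000, seed = 1,
                                   age = 51.46, male = 0.783, nbds_range = 0:47) {
  rows <- purrr::map(nbds_range, function(j) {
    r <- simulate_expected_utility(model, j, value_set, trials, seed, age, male)
    tibble(nbds = j, utility = r$utility, mc_se = r$mc_se, trials = r$trials)
  })
  out <- bind_rows(rows)
  structure(out, class = c("nbd_utility_curve", class(out)))
}

#' State utilities derived from a utility curve
#'
#' Looks up the expected-utility curve at the health-state NBDS scores:
#' standard care at the baseline score, TAI responders at baseline plus the
#' responder improvement, TAI non-responders at baseline plus the
#' deterioration.  Non-integer target scores are rounded half-up; scores
#' pushed outside 0-47 are clamped with a warning.  This is the derived
#' alternative to the packaged base-case state utilities.
#'
#' @param curve An `nbd_utility_curve` (or tibble with `nbds`, `utility`).
#' @param nbds_baseline Baseline NBDS (default 16.74).
#' @param deltas Numeric vector `c(responder, nonresponder)` NBDS changes
#'   (default `c(-6, 1)`).
#' @return A named list with `u_responder`, `u_nonresponder`, `u_sbc` and the
#'   looked-up scores.
#' @export
state_utilities_from_curve <- function(curve, nbds_baseline = 16.74,
                                       deltas = c(-6, 1)) {
  lookup <- function(score) {
    j <- floor(score + 0.5)
    if (j < 0 || j > 47) {
      warn(sprintf("NBDS target %g outside 0-47; clamped", j))
      j <- pmin(pmax(j, 0), 47)
    }
    if (!j %in% curve$nbds) abort(sprintf("curve does not cover NBDS %d", j))
    list(score = j, utility = curve$utility[curve$nbds == j])
  }
  r <- lookup(nbds_baseline + deltas[1])
  n <- lookup(nbds_baseline + deltas[2])
  s <- lookup(nbds_baseline)
  list(u_responder = r$utility, u_nonresponder = n$utility, u_sbc = s$utility,
       scores = c(responder = r$score, nonresponder = n$score, sbc = s$score))
}

#' @export
tidy.eq5d_mapping <- function(x, ...) {
  rows <- purrr::imap(x$dimensions, function(f, d) {
    if (f$type == "degenerate")
      return(tibble(dimension = d, level = f$level, term = "(degenerate)",
                    estimate = NA_real_))
    co <- coef(f$fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1, dimnames = list(f$levels[-1], names(co)))
    as_tibble(co, rownames = "level") %>%
      mutate(level = as.integer(level), dimension = d) %>%
      tidyr::pivot_longer(-c(dimension, level), names_to = "term",
                          values_to = "estimate")
  })
  bind_rows(rows)
}

#' @export
glance.eq5d_mapping <- function(x, ...) {
  tibble(dimension = names(x$dimensions),
         type = purrr::map_chr(x$dimensions, "type"),
         n_levels = purrr::map_int(x$dimensions, ~ length(.x$levels)),
         converged = purrr::map_lgl(x$dimensions, "converged"))
}
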